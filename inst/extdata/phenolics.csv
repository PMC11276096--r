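cultivar,analyte,analyte_class,mean,sd,n,unit
Gala,A,phenolic,0.24,0.41,3,mg/kg FW
Red Jonaprince,A,phenolic,0.86,0.58,3,mg/kg FW
Red Delicious,A,phenolic,n.d.,n.d.,3,mg/kg FW
Fuji,A,phenolic,n.d.,n.d.,3,mg/kg FW
Granny Smith,A,phenolic,n.d.,n.d.,3,mg/kg FW
Idared,A,phenolic,0.21,0.36,3,mg/kg FW
Golden Delicious,A,phenolic,0.29,0.49,3,mg/kg FW
Gala,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Red Jonaprince,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Red Delicious,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Fuji,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Granny Smith,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Idared,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Golden Delicious,HBA,phenolic,n.d.,n.d.,3,mg/kg FW
Gala,GA,phenolic,0.17,0.07,3,mg/kg FW
Red Jonaprince,GA,phenolic,0.14,0.04,3,mg/kg FW
Red Delicious,GA,phenolic,0.56,0.13,3,mg/kg FW
Fuji,GA,phenolic,0.16,0.12,3,mg/kg FW
Granny Smith,GA,phenolic,0.18,0.03,3,mg/kg FW
Idared,GA,phenolic,0.22,0.05,3,mg/kg FW
Golden Delicious,GA,phenolic,0.10,0.09,3,mg/kg FW
Gala,pCA,phenolic,2.57,0.53,3,mg/kg FW
Red Jonaprince,pCA,phenolic,1.72,0.53,3,mg/kg FW
Red Delicious,pCA,phenolic,2.15,0.42,3,mg/kg FW
Fuji,pCA,phenolic,1.33,0.07,3,mg/kg FW
Granny Smith,pCA,phenolic,n.d.,n.d.,3,mg/kg FW
Idared,pCA,phenolic,3.14,0.16,3,mg/kg FW
Golden Delicious,pCA,phenolic,2.36,0.18,3,mg/kg FW
Gala,CA,phenolic,156.37,46.01,3,mg/kg FW
Red Jonaprince,CA,phenolic,94.93,30.04,3,mg/kg FW
Red Delicious,CA,phenolic,75.90,15.06,3,mg/kg FW
Fuji,CA,phenolic,104.52,5.22,3,mg/kg FW
Granny Smith,CA,phenolic,30.24,8.71,3,mg/kg FW
Idared,CA,phenolic,162.72,10.27,3,mg/kg FW
Golden Delicious,CA,phenolic,97.49,14.88,3,mg/kg FW
Gala,nCA,phenolic,n.d.,n.d.,3,mg/kg FW
Red Jonaprince,nCA,phenolic,n.d.,n.d.,3,mg/kg FW
Red Delicious,nCA,phenolic,n.d.,n.d.,3,mg/kg FW
Fuji,nCA,phenolic,n.d.,n.d.,3,mg/kg FW
Granny Smith,nCA,phenolic,n.d.,n.d.,3,mg/kg FW
Idared,nCA,phenolic,n.d.,n.d.,3,mg/kg FW
Golden Delicious,nCA,phenolic,0.17,0.03,3,mg/kg FW
Gala,C,phenolic,9.46,4.10,3,mg/kg FW
Red Jonaprince,C,phenolic,3.02,0.63,3,mg/kg FW
Red Delicious,C,phenolic,13.02,1.67,3,mg/kg FW
Fuji,C,phenolic,5.57,0.90,3,mg/kg FW
Granny Smith,C,phenolic,21.19,1.48,3,mg/kg FW
Idared,C,phenolic,8.89,1.64,3,mg/kg FW
Golden Delicious,C,phenolic,4.02,0.16,3,mg/kg FW
Gala,E,phenolic,31.04,4.79,3,mg/kg FW
Red Jonaprince,E,phenolic,26.40,4.13,3,mg/kg FW
Red Delicious,E,phenolic,48.92,6.21,3,mg/kg FW
Fuji,E,phenolic,36.79,4.46,3,mg/kg FW
Granny Smith,E,phenolic,59.53,7.65,3,mg/kg FW
Idared,E,phenolic,27.58,2.35,3,mg/kg FW
Golden Delicious,E,phenolic,32.88,2.82,3,mg/kg FW
Gala,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Red Jonaprince,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Red Delicious,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Fuji,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Granny Smith,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Idared,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Golden Delicious,pCB1,phenolic,n.d.,n.d.,3,mg/kg FW
Gala,pCB2,phenolic,64.17,9.27,3,mg/kg FW
Red Jonaprince,pCB2,phenolic,56.47,9.91,3,mg/kg FW
Red Delicious,pCB2,phenolic,73.11,5.93,3,mg/kg FW
Fuji,pCB2,phenolic,58.38,11.66,3,mg/kg FW
Granny Smith,pCB2,phenolic,92.96,24.12,3,mg/kg FW
Idared,pCB2,phenolic,54.92,3.96,3,mg/kg FW
Golden Delicious,pCB2,phenolic,58.92,4.51,3,mg/kg FW
Gala,Q3ga,phenolic,6.96,2.91,3,mg/kg FW
Red Jonaprince,Q3ga,phenolic,9.14,7.73,3,mg/kg FW
Red Delicious,Q3ga,phenolic,8.25,4.18,3,mg/kg FW
Fuji,Q3ga,phenolic,3.17,2.01,3,mg/kg FW
Granny Smith,Q3ga,phenolic,8.06,3.58,3,mg/kg FW
Idared,Q3ga,phenolic,4.68,2.92,3,mg/kg FW
Golden Delicious,Q3ga,phenolic,3.87,5.21,3,mg/kg FW
Gala,Q3gl,phenolic,1.72,0.50,3,mg/kg FW
Red Jonaprince,Q3gl,phenolic,2.21,1.48,3,mg/kg FW
Red Delicious,Q3gl,phenolic,1.34,0.49,3,mg/kg FW
Fuji,Q3gl,phenolic,2.33,2.78,3,mg/kg FW
Granny Smith,Q3gl,phenolic,2.78,0.92,3,mg/kg FW
Idared,Q3gl,phenolic,1.00,0.10,3,mg/kg FW
Golden Delicious,Q3gl,phenolic,1.37,1.05,3,mg/kg FW
Gala,Q3ru,phenolic,7.52,2.33,3,mg/kg FW
Red Jonaprince,Q3ru,phenolic,7.93,4.48,3,mg/kg FW
Red Delicious,Q3ru,phenolic,5.90,1.82,3,mg/kg FW
Fuji,Q3ru,phenolic,3.13,1.33,3,mg/kg FW
Granny Smith,Q3ru,phenolic,5.88,2.03,3,mg/kg FW
Idared,Q3ru,phenolic,4.27,0.68,3,mg/kg FW
Golden Delicious,Q3ru,phenolic,2.85,2.03,3,mg/kg FW
Gala,Q3rh,phenolic,10.41,5.91,3,mg/kg FW
Red Jonaprince,Q3rh,phenolic,22.90,11.46,3,mg/kg FW
Red Delicious,Q3rh,phenolic,5.69,1.57,3,mg/kg FW
Fuji,Q3rh,phenolic,4.40,1.66,3,mg/kg FW
Granny Smith,Q3rh,phenolic,8.19,1.95,3,mg/kg FW
Idared,Q3rh,phenolic,4.96,1.17,3,mg/kg FW
Golden Delicious,Q3rh,phenolic,8.79,3.32,3,mg/kg FW
Gala,P,phenolic,18.97,4.32,3,mg/kg FW
Red Jonaprince,P,phenolic,12.85,2.42,3,mg/kg FW
Red Delicious,P,phenolic,23.92,8.34,3,mg/kg FW
Fuji,P,phenolic,8.25,1.21,3,mg/kg FW
Granny Smith,P,phenolic,5.58,3.37,3,mg/kg FW
Idared,P,phenolic,13.00,1.61,3,mg/kg FW
Golden Delicious,P,phenolic,10.78,2.67,3,mg/kg FW
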