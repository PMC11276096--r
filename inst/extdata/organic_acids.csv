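cultivar,analyte,analyte_class,mean,sd,n,unit
Gala,QA,organic_acid,178.78,79.73,3,mg/kg FW
Red Jonaprince,QA,organic_acid,132.01,27.29,3,mg/kg FW
Red Delicious,QA,organic_acid,526.77,29.59,3,mg/kg FW
Fuji,QA,organic_acid,127.30,16.94,3,mg/kg FW
Granny Smith,QA,organic_acid,151.01,25.27,3,mg/kg FW
Idared,QA,organic_acid,76.33,16.13,3,mg/kg FW
Golden Delicious,QA,organic_acid,88.31,20.20,3,mg/kg FW
Gala,LA,organic_acid,69.39,27.04,3,mg/kg FW
Red Jonaprince,LA,organic_acid,n.d.,n.d.,3,mg/kg FW
Red Delicious,LA,organic_acid,165.25,89.55,3,mg/kg FW
Fuji,LA,organic_acid,93.05,30.25,3,mg/kg FW
Granny Smith,LA,organic_acid,101.74,40.03,3,mg/kg FW
Idared,LA,organic_acid,86.22,55.78,3,mg/kg FW
Golden Delicious,LA,organic_acid,n.d.,n.d.,3,mg/kg FW
Gala,ShA,organic_acid,69.35,14.06,3,mg/kg FW
Red Jonaprince,ShA,organic_acid,74.05,11.73,3,mg/kg FW
Red Delicious,ShA,organic_acid,208.96,120.63,3,mg/kg FW
Fuji,ShA,organic_acid,312.73,132.77,3,mg/kg FW
Granny Smith,ShA,organic_acid,411.66,405.67,3,mg/kg FW
Idared,ShA,organic_acid,114.51,7.08,3,mg/kg FW
Golden Delicious,ShA,organic_acid,68.07,17.10,3,mg/kg FW
Gala,GA,organic_acid,n.d.,n.d.,3,mg/kg FW
Red Jonaprince,GA,organic_acid,37.03,49.62,3,mg/kg FW
Red Delicious,GA,organic_acid,n.d.,n.d.,3,mg/kg FW
Fuji,GA,organic_acid,n.d.,n.d.,3,mg/kg FW
Granny Smith,GA,organic_acid,n.d.,n.d.,3,mg/kg FW
Idared,GA,organic_acid,n.d.,n.d.,3,mg/kg FW
Golden Delicious,GA,organic_acid,181.46,36.12,3,mg/kg FW
Gala,SuA,organic_acid,126.82,64.23,3,mg/kg FW
Red Jonaprince,SuA,organic_acid,146.36,110.31,3,mg/kg FW
Red Delicious,SuA,organic_acid,193.57,28.07,3,mg/kg FW
Fuji,SuA,organic_acid,127.64,53.78,3,mg/kg FW
Granny Smith,SuA,organic_acid,119.04,17.80,3,mg/kg FW
Idared,SuA,organic_acid,169.18,10.56,3,mg/kg FW
Golden Delicious,SuA,organic_acid,161.66,7.72,3,mg/kg FW
Gala,MA,organic_acid,4023.98,631.65,3,mg/kg FW
Red Jonaprince,MA,organic_acid,3138.72,687.10,3,mg/kg FW
Red Delicious,MA,organic_acid,2744.00,656.17,3,mg/kg FW
Fuji,MA,organic_acid,4771.05,453.67,3,mg/kg FW
Granny Smith,MA,organic_acid,6958.48,484.10,3,mg/kg FW
Idared,MA,organic_acid,6359.65,752.74,3,mg/kg FW
Golden Delicious,MA,organic_acid,5860.42,435.24,3,mg/kg FW
Gala,FA,organic_acid,34.35,19.07,3,mg/kg FW
Red Jonaprince,FA,organic_acid,32.71,3.01,3,mg/kg FW
Red Delicious,FA,organic_acid,62.72,37.33,3,mg/kg FW
Fuji,FA,organic_acid,304.87,219.17,3,mg/kg FW
Granny Smith,FA,organic_acid,71.97,33.62,3,mg/kg FW
Idared,FA,organic_acid,48.58,34.91,3,mg/kg FW
Golden Delicious,FA,organic_acid,51.49,12.78,3,mg/kg FW
Gala,OA,organic_acid,16.54,4.08,3,mg/kg FW
Red Jonaprince,OA,organic_acid,24.40,10.08,3,mg/kg FW
Red Delicious,OA,organic_acid,14.36,10.40,3,mg/kg FW
Fuji,OA,organic_acid,25.82,3.98,3,mg/kg FW
Granny Smith,OA,organic_acid,16.25,2.01,3,mg/kg FW
Idared,OA,organic_acid,44.40,42.71,3,mg/kg FW
Golden Delicious,OA,organic_acid,16.91,4.60,3,mg/kg FW
Gala,CA,organic_acid,47.65,5.84,3,mg/kg FW
Red Jonaprince,CA,organic_acid,47.12,10.35,3,mg/kg FW
Red Delicious,CA,organic_acid,52.46,43.57,3,mg/kg FW
Fuji,CA,organic_acid,91.55,29.44,3,mg/kg FW
Granny Smith,CA,organic_acid,106.01,29.60,3,mg/kg FW
Idared,CA,organic_acid,94.80,11.84,3,mg/kg FW
Golden Delicious,CA,organic_acid,131.87,10.45,3,mg/kg FW
Gala,P,organic_acid,118.66,25.08,3,mg/kg FW
Red Jonaprince,P,organic_acid,102.34,38.61,3,mg/kg FW
Red Delicious,P,organic_acid,136.98,38.49,3,mg/kg FW
Fuji,P,organic_acid,238.18,56.27,3,mg/kg FW
Granny Smith,P,organic_acid,195.22,106.25,3,mg/kg FW
Idared,P,organic_acid,151.25,6.00,3,mg/kg FW
Golden Delicious,P,organic_acid,248.49,27.61,3,mg/kg FW
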