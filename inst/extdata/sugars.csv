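cultivar,analyte,analyte_class,mean,sd,n,unit
Gala,Glu,sugar,20.95,0.70,3,g/kg FW
Red Jonaprince,Glu,sugar,24.42,4.92,3,g/kg FW
Red Delicious,Glu,sugar,21.11,1.68,3,g/kg FW
Fuji,Glu,sugar,21.89,1.77,3,g/kg FW
Granny Smith,Glu,sugar,16.29,0.87,3,g/kg FW
Idared,Glu,sugar,18.81,1.26,3,g/kg FW
Golden Delicious,Glu,sugar,14.64,1.85,3,g/kg FW
Gala,Fru,sugar,54.43,3.84,3,g/kg FW
Red Jonaprince,Fru,sugar,52.87,9.41,3,g/kg FW
Red Delicious,Fru,sugar,40.52,2.92,3,g/kg FW
Fuji,Fru,sugar,49.89,3.37,3,g/kg FW
Granny Smith,Fru,sugar,34.60,1.30,3,g/kg FW
Idared,Fru,sugar,55.61,1.51,3,g/kg FW
Golden Delicious,Fru,sugar,52.62,4.47,3,g/kg FW
Gala,Suc,sugar,15.84,0.53,3,g/kg FW
Red Jonaprince,Suc,sugar,20.04,4.59,3,g/kg FW
Red Delicious,Suc,sugar,22.20,2.20,3,g/kg FW
Fuji,Suc,sugar,22.77,1.52,3,g/kg FW
Granny Smith,Suc,sugar,24.77,1.17,3,g/kg FW
Idared,Suc,sugar,28.45,4.70,3,g/kg FW
Golden Delicious,Suc,sugar,32.92,2.41,3,g/kg FW
Gala,Gal,sugar,n.d.,n.d.,3,g/kg FW
Red Jonaprince,Gal,sugar,n.d.,n.d.,3,g/kg FW
Red Delicious,Gal,sugar,n.d.,n.d.,3,g/kg FW
Fuji,Gal,sugar,n.d.,n.d.,3,g/kg FW
Granny Smith,Gal,sugar,n.d.,n.d.,3,g/kg FW
Idared,Gal,sugar,n.d.,n.d.,3,g/kg FW
Golden Delicious,Gal,sugar,n.d.,n.d.,3,g/kg FW
Gala,S,sugar_alcohol,2.61,0.52,3,g/kg FW
Red Jonaprince,S,sugar_alcohol,3.62,1.56,3,g/kg FW
Red Delicious,S,sugar_alcohol,3.47,0.20,3,g/kg FW
Fuji,S,sugar_alcohol,2.87,0.64,3,g/kg FW
Granny Smith,S,sugar_alcohol,2.31,1.55,3,g/kg FW
Idared,S,sugar_alcohol,3.57,0.43,3,g/kg FW
Golden Delicious,S,sugar_alcohol,3.58,0.09,3,g/kg FW
Gala,MI,sugar_alcohol,0.59,0.12,3,g/kg FW
Red Jonaprince,MI,sugar_alcohol,0.48,0.06,3,g/kg FW
Red Delicious,MI,sugar_alcohol,0.82,0.05,3,g/kg FW
Fuji,MI,sugar_alcohol,0.47,0.10,3,g/kg FW
Granny Smith,MI,sugar_alcohol,0.81,0.04,3,g/kg FW
Idared,MI,sugar_alcohol,0.69,0.11,3,g/kg FW
Golden Delicious,MI,sugar_alcohol,0.85,0.11,3,g/kg FW
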