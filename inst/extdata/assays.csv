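cultivar,analyte,analyte_class,mean,sd,n,unit
Gala,TPC,assay_endpoint,620.67,57.55,3,mg GAE/kg FW
Red Jonaprince,TPC,assay_endpoint,972.74,182.74,3,mg GAE/kg FW
Red Delicious,TPC,assay_endpoint,844.98,13.26,3,mg GAE/kg FW
Fuji,TPC,assay_endpoint,696.61,24.74,3,mg GAE/kg FW
Granny Smith,TPC,assay_endpoint,579.39,24.28,3,mg GAE/kg FW
Idared,TPC,assay_endpoint,807.63,6.56,3,mg GAE/kg FW
Golden Delicious,TPC,assay_endpoint,692.12,7.75,3,mg GAE/kg FW
Gala,DPPH_IC50,assay_endpoint,360.94,88.65,3,ug/mL
Red Jonaprince,DPPH_IC50,assay_endpoint,399.35,90.15,3,ug/mL
Red Delicious,DPPH_IC50,assay_endpoint,302.67,9.66,3,ug/mL
Fuji,DPPH_IC50,assay_endpoint,435.26,40.25,3,ug/mL
Granny Smith,DPPH_IC50,assay_endpoint,1182.17,275.04,3,ug/mL
Idared,DPPH_IC50,assay_endpoint,349.43,9.68,3,ug/mL
Golden Delicious,DPPH_IC50,assay_endpoint,439.95,50.76,3,ug/mL
Gala,FRAP,assay_endpoint,210.41,42.19,3,mg AAE/kg FW
Red Jonaprince,FRAP,assay_endpoint,347.29,95.26,3,mg AAE/kg FW
Red Delicious,FRAP,assay_endpoint,267.22,26.81,3,mg AAE/kg FW
Fuji,FRAP,assay_endpoint,311.18,44.11,3,mg AAE/kg FW
Granny Smith,FRAP,assay_endpoint,300.82,52.30,3,mg AAE/kg FW
Idared,FRAP,assay_endpoint,318.10,40.76,3,mg AAE/kg FW
Golden Delicious,FRAP,assay_endpoint,214.14,29.56,3,mg AAE/kg FW
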