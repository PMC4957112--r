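dataset,n,n_features,rf,rbf
Computer hardware,209,7,59.66,58.39
Yacht hydrodynamics,308,6,1.00,1.00
Housing,506,12,3.07,3.13
Forest fire,517,13,1.41,1.40
Istanbul stock exchange,536,8,0.01,0.01
Concrete compressive strength,1030,9,4.53,4.18
Parkinsons telemonitoring,5875,19,1.65,1.19
Wine quality,6497,11,0.58,0.57
Bike sharing,17389,16,39.97,38.26
Buzz in social media tomhardware,28179,97,0.31,0.31
Physicochemical properties,45730,9,3.45,3.27
3D Road Network,434874,2,3.86,1.20
Year prediction MSD,515345,90,9.24,8.87
Buzz in social media twitter,583250,78,0.47,0.47
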