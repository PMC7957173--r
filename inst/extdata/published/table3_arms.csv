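# Published per-arm discounted results (USD, QALYs) by trial and horizon.
trial,horizon_years,arm,cost,qaly,acer,net_benefit
archer1050,5,dacomitinib,91798.60,1.83,50214.97,-35441.56
archer1050,5,gefitinib,43296.13,1.80,24019.32,12273.01
flaura,5,osimertinib,63933.01,1.56,40937.92,-15788.73
flaura,5,egfr_tki,29583.24,1.48,19998.87,16018.95
jo25567,5,bev_erlotinib,99859.26,1.33,75160.74,-58900.90
jo25567,5,erlotinib,28690.10,1.48,19416.41,16862.01
nej026,5,bev_erlotinib,99392.65,1.33,74573.71,-58304.76
nej026,5,erlotinib,27601.34,1.49,18556.46,18252.99
nej009,5,gef_carbo_pem,75379.85,1.36,55239.44,-33311.89
nej009,5,gefitinib,40830.75,1.49,27416.56,5080.57
nct02148380,5,pem_carbo_gef,62569.47,1.71,36485.62,-9702.30
nct02148380,5,pem_carbo,48901.81,1.75,27957.76,5020.42
nct02148380,5,gefitinib,39191.20,1.85,21163.42,17897.22
archer1050,10,dacomitinib,107379.86,2.14,50214.97,-41457.16
archer1050,10,gefitinib,50644.91,2.11,24019.32,14356.15
flaura,10,osimertinib,69941.25,1.71,40937.92,-17272.51
flaura,10,egfr_tki,32363.39,1.62,19998.87,17524.36
jo25567,10,bev_erlotinib,109243.75,1.45,75160.74,-64436.23
jo25567,10,erlotinib,31386.31,1.62,19416.41,18446.65
nej026,10,bev_erlotinib,108733.29,1.46,74573.71,-63784.07
nej026,10,erlotinib,30195.23,1.63,18556.46,19968.35
nej009,10,gef_carbo_pem,82463.82,1.49,55239.44,-36442.45
nej009,10,gefitinib,44667.91,1.63,27416.56,5558.03
nct02148380,10,pem_carbo_gef,73189.59,2.01,36485.62,-11349.10
nct02148380,10,pem_carbo,57202.06,2.05,27957.76,5872.56
nct02148380,10,gefitinib,45843.25,2.17,21163.42,20934.97
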