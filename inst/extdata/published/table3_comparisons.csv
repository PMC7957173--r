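# Published pairwise comparisons (incremental cost/effect/ICER) by trial
# and horizon. ic_note records whether the printed IC equals the printed
# cost difference exactly or differs by one cent of rounding.
trial,horizon_years,treat,ctrl,ic,ie,icer,ic_note
archer1050,5,dacomitinib,gefitinib,48502.47,0.03,1897750.74,exact
flaura,5,osimertinib,egfr_tki,34349.77,0.08,416560.02,exact
jo25567,5,bev_erlotinib,erlotinib,71169.17,-0.15,-477607.48,rounded
nej026,5,bev_erlotinib,erlotinib,71791.31,-0.15,-464326.66,exact
nej009,5,gef_carbo_pem,gefitinib,34549.09,-0.12,-277121.22,rounded
nct02148380,5,pem_carbo_gef,pem_carbo,13667.67,-0.03,-399360.94,rounded
nct02148380,5,pem_carbo_gef,gefitinib,23378.27,-0.14,-170733.05,exact
archer1050,10,dacomitinib,gefitinib,56734.94,0.03,1897750.74,rounded
flaura,10,osimertinib,egfr_tki,37577.86,0.09,416560.02,exact
jo25567,10,bev_erlotinib,erlotinib,77857.44,-0.16,-477607.48,exact
nej026,10,bev_erlotinib,erlotinib,78538.05,-0.17,-464326.66,rounded
nej009,10,gef_carbo_pem,gefitinib,37795.92,-0.14,-277121.22,rounded
nct02148380,10,pem_carbo_gef,pem_carbo,15987.53,-0.04,-399360.94,exact
nct02148380,10,pem_carbo_gef,gefitinib,27346.34,-0.16,-170733.05,exact
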