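id,enzyme_label,equation,lb,ub,dg0_prime,is_exchange,is_objective
glyk,glyk,glyc_c + atp_c -> glyc3p_c + adp_c,0,10,-18,FALSE,FALSE
g3pd,gly3pdh,glyc3p_c + nad_c -> dhap_c + nadh_c,0,10,-25,FALSE,FALSE
tpi,tpi,dhap_c <-> gap_c,-10,10,5.5,FALSE,FALSE
fba,fba,fdp_c <-> dhap_c + gap_c,-10,10,21,FALSE,FALSE
pfk,pfk,f6p_c + atp_c -> fdp_c + adp_c,0,10,-16,FALSE,FALSE
fbp,fbpase,fdp_c -> f6p_c + pi_c,0,10,-11,FALSE,FALSE
pgi,pgi,g6p_c <-> f6p_c,-10,10,2.5,FALSE,FALSE
gapd,gapdh,gap_c + nad_c + pi_c <-> dpg13_c + nadh_c,-10,10,6.3,FALSE,FALSE
pgk,pgk,dpg13_c + adp_c <-> pg3_c + atp_c,-10,10,-18.9,FALSE,FALSE
pgm,pgm,pg3_c <-> pg2_c,-10,10,4.4,FALSE,FALSE
eno,eno,pg2_c <-> pep_c,-10,10,-3.2,FALSE,FALSE
pyk,pyk,pep_c + adp_c -> pyr_c + atp_c,0,10,-27,FALSE,FALSE
pps,pps,pyr_c + atp_c -> pep_c + adp_c + pi_c,0,10,-10,FALSE,FALSE
pdh,pdh,pyr_c + coa_c + nad_c -> accoa_c + nadh_c + co2_e,0,10,-34,FALSE,FALSE
pck,pck,oaa_c + atp_c -> pep_c + adp_c + co2_e,0,10,-3,FALSE,FALSE
mgsa,mgsa,dhap_c -> mgo_c + pi_c,0,10,-12,FALSE,FALSE
glyox,glyox,mgo_c -> lac__D_c,0,10,-55,FALSE,FALSE
ldh,ldh,lac__D_c + nad_c -> pyr_c + nadh_c,0,10,-16,FALSE,FALSE
cs,cs,accoa_c + oaa_c -> cit_c + coa_c,0,10,-36,FALSE,FALSE
icd,icd,cit_c + nadp_c -> akg_c + nadph_c + co2_e,0,10,-6,FALSE,FALSE
akgd,akgdh,akg_c + nad_c + adp_c + pi_c -> succ_c + nadh_c + atp_c + co2_e,0,10,-28,FALSE,FALSE
sdh,sdh,succ_c + nad_c -> mal__L_c + nadh_c,0,10,-6,FALSE,FALSE
mdh,mdh,mal__L_c + nad_c <-> oaa_c + nadh_c,-10,10,8,FALSE,FALSE
ppc,ppc,pep_c + co2_e -> oaa_c + pi_c,0,10,-28,FALSE,FALSE
zwf,zwf,g6p_c + nadp_c -> pgc6_c + nadph_c,0,10,-22,FALSE,FALSE
gnd,gnd,pgc6_c + nadp_c -> ru5p__D_c + nadph_c + co2_e,0,10,-10,FALSE,FALSE
rpe,rpe,ru5p__D_c <-> xu5p__D_c,-10,10,0.5,FALSE,FALSE
rpi,rpi,ru5p__D_c <-> r5p_c,-10,10,-2,FALSE,FALSE
tkt1,tkt,r5p_c + xu5p__D_c <-> s7p_c + gap_c,-10,10,-3.8,FALSE,FALSE
tal,tal,s7p_c + gap_c <-> e4p_c + f6p_c,-10,10,-0.9,FALSE,FALSE
prpps,prpps,r5p_c + atp_c -> prpp_c + adp_c,0,10,-6,FALSE,FALSE
sera,serA,pg3_c + nad_c + glu__L_c -> pser__L_c + nadh_c + akg_c,0,10,2,FALSE,FALSE
psp_L,psp_L,pser__L_c -> ser__L_c + pi_c,0,10,-12,FALSE,FALSE
glya,glyA,ser__L_c <-> gly_c,-10,10,1,FALSE,FALSE
dahpts,dahpts,pep_c + e4p_c -> dahp_c + pi_c,0,10,-25,FALSE,FALSE
dhqs,dhqs,dahp_c -> dhs3_c + pi_c,0,10,-15,FALSE,FALSE
shkdh,shkdh,dhs3_c + nadph_c + atp_c -> s3p_c + nadp_c + adp_c,0,10,-10,FALSE,FALSE
pscvt,pscvt,s3p_c + pep_c -> epsp_c + pi_c,0,10,-8,FALSE,FALSE
chors,chors,epsp_c -> chor_c + pi_c,0,10,-25,FALSE,FALSE
anths,anths,chor_c + nh4_c -> anth_c + pyr_c,0,10,-15,FALSE,FALSE
anprt,anprt,anth_c + prpp_c -> cdrp_c + ppi_c,0,10,-10,FALSE,FALSE
igps,igps,cdrp_c -> igp_c + co2_e,0,10,-25,FALSE,FALSE
trps2,trps2,igp_c + ser__L_c -> trp__L_c + gap_c,0,10,-20,FALSE,FALSE
ppndh,ppndh,chor_c + glu__L_c -> phe__L_e + akg_c + co2_e,0,10,-40,FALSE,FALSE
growth,biomass,0.205 g6p_c + 0.071 f6p_c + 0.090 r5p_c + 0.036 e4p_c + 0.150 pg3_c + 0.052 pep_c + 0.283 pyr_c + 0.305 accoa_c + 0.179 oaa_c + 0.107 akg_c + 0.100 ser__L_c + 0.058 gly_c + 41.0 atp_c + 1.8 nadph_c -> 41.0 adp_c + 41.0 pi_c + 1.8 nadp_c + 0.305 coa_c + 0.3 nadh_c,0,2,NA,FALSE,TRUE
glyc_upt,glycerol uptake,glyc_e -> glyc_c,0,10,NA,TRUE,FALSE
glc_pts,glucose PTS,glc__D_e + pep_c -> g6p_c + pyr_c,0,10,NA,TRUE,FALSE
pyr_upt,pyruvate uptake,pyr_e -> pyr_c,0,10,NA,TRUE,FALSE
succ_upt,succinate uptake,succ_e -> succ_c,0,10,NA,TRUE,FALSE
trp_sec,L-trp secretion,trp__L_c -> trp__L_e,0,10,NA,TRUE,FALSE
ac_sec,acetate secretion,accoa_c + adp_c + pi_c -> ac_e + atp_c + coa_c,0,10,NA,TRUE,FALSE
o2_upt,O2 uptake,o2_e ->,0,50,NA,TRUE,FALSE
co2_sec,CO2 secretion,-> co2_e,0,50,NA,TRUE,FALSE
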