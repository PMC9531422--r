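id,name,compartment,conc_lb,conc_ub,is_balanced,measured
glyc_c,glycerol,cytosol,1e-7,0.1,TRUE,TRUE
glyc3p_c,sn-glycerol 3-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
dhap_c,dihydroxyacetone phosphate,cytosol,1e-7,0.1,TRUE,TRUE
gap_c,glyceraldehyde 3-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
fdp_c,"fructose 1,6-bisphosphate",cytosol,1e-7,0.1,TRUE,TRUE
f6p_c,fructose 6-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
g6p_c,glucose 6-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
dpg13_c,"1,3-bisphosphoglycerate",cytosol,1e-7,0.1,TRUE,TRUE
pg3_c,3-phosphoglycerate,cytosol,1e-7,0.1,TRUE,TRUE
pg2_c,2-phosphoglycerate,cytosol,1e-7,0.1,TRUE,TRUE
pep_c,phosphoenolpyruvate,cytosol,1e-7,0.1,TRUE,TRUE
pyr_c,pyruvate,cytosol,1e-7,0.1,TRUE,TRUE
mgo_c,methylglyoxal,cytosol,1e-7,0.1,TRUE,TRUE
lac__D_c,D-lactate,cytosol,1e-7,0.1,TRUE,TRUE
accoa_c,acetyl-CoA,cytosol,1e-7,0.1,TRUE,TRUE
cit_c,citrate,cytosol,1e-7,0.1,TRUE,TRUE
akg_c,2-oxoglutarate,cytosol,1e-7,0.1,TRUE,TRUE
succ_c,succinate,cytosol,1e-7,0.1,TRUE,TRUE
mal__L_c,L-malate,cytosol,1e-7,0.1,TRUE,TRUE
oaa_c,oxaloacetate,cytosol,1e-7,0.1,TRUE,TRUE
pgc6_c,6-phosphogluconate,cytosol,1e-7,0.1,TRUE,TRUE
ru5p__D_c,ribulose 5-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
r5p_c,ribose 5-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
xu5p__D_c,xylulose 5-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
s7p_c,sedoheptulose 7-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
e4p_c,erythrose 4-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
prpp_c,5-phospho-alpha-D-ribose 1-diphosphate,cytosol,1e-7,0.1,TRUE,TRUE
pser__L_c,O-phospho-L-serine,cytosol,1e-7,0.1,TRUE,TRUE
ser__L_c,L-serine,cytosol,1e-7,0.1,TRUE,TRUE
gly_c,glycine,cytosol,1e-7,0.1,TRUE,TRUE
dahp_c,3-deoxy-D-arabino-heptulosonate 7-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
dhs3_c,3-dehydroshikimate,cytosol,1e-7,0.1,TRUE,TRUE
s3p_c,shikimate 3-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
epsp_c,5-enolpyruvylshikimate 3-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
chor_c,chorismate,cytosol,1e-7,0.1,TRUE,TRUE
anth_c,anthranilate,cytosol,1e-7,0.1,TRUE,TRUE
cdrp_c,1-(2-carboxyphenylamino)-1-deoxy-D-ribulose 5-phosphate,cytosol,1e-7,0.1,TRUE,TRUE
igp_c,indole-3-glycerol phosphate,cytosol,1e-7,0.1,TRUE,TRUE
trp__L_c,L-tryptophan,cytosol,1e-7,0.1,TRUE,TRUE
atp_c,ATP,cytosol,1e-7,0.1,FALSE,TRUE
nad_c,NAD+,cytosol,1e-7,0.1,FALSE,TRUE
nadh_c,NADH,cytosol,1e-7,0.1,FALSE,TRUE
nadph_c,NADPH,cytosol,1e-7,0.1,FALSE,TRUE
glu__L_c,L-glutamate,cytosol,1e-7,0.1,FALSE,TRUE
pi_c,orthophosphate,cytosol,1e-7,0.1,FALSE,TRUE
adp_c,ADP,cytosol,1e-7,0.1,FALSE,FALSE
nadp_c,NADP+,cytosol,1e-7,0.1,FALSE,FALSE
coa_c,coenzyme A,cytosol,1e-7,0.1,FALSE,FALSE
nh4_c,ammonium,cytosol,1e-7,0.1,FALSE,FALSE
ppi_c,diphosphate,cytosol,1e-7,0.1,FALSE,FALSE
glyc_e,glycerol (extracellular),extracellular,1e-7,1,FALSE,FALSE
glc__D_e,D-glucose (extracellular),extracellular,1e-7,1,FALSE,FALSE
pyr_e,pyruvate (extracellular),extracellular,1e-7,1,FALSE,FALSE
succ_e,succinate (extracellular),extracellular,1e-7,1,FALSE,FALSE
trp__L_e,L-tryptophan (extracellular),extracellular,1e-7,1,FALSE,FALSE
ac_e,acetate (extracellular),extracellular,1e-7,1,FALSE,FALSE
phe__L_e,L-phenylalanine (extracellular),extracellular,1e-7,1,FALSE,FALSE
o2_e,oxygen (extracellular),extracellular,1e-7,1,FALSE,FALSE
co2_e,carbon dioxide (extracellular),extracellular,1e-7,1,FALSE,FALSE
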