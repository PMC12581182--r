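ligand,receptor,direction
ICOSL,ICOS,tme_to_t
CD80,CTLA4,tme_to_t
CD86,CTLA4,tme_to_t
PDL1,PD1,tme_to_t
PDL2,PD1,tme_to_t
OX40L,OX40,tme_to_t
CD137L,CD137,tme_to_t
PVR,TIGIT,tme_to_t
CD95L,CD95,tme_to_t
HVEM,BTLA,tme_to_t
GAL9,TIM3,tme_to_t
CD40L,CD40,t_to_tme
CD80,CD28,tme_to_t
CD86,CD28,tme_to_t
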