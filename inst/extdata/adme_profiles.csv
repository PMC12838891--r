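compound,mw,logp_consensus,logp_max_method,log_s,ba_score,hbd,hba,tpsa,ionization,lipinski_violations,ghose_violations,muegge_violations,alerts,gi_absorption,sa_score,provenance
ICLID,603.66,4.53,6.72,-7.80,0.55,1,6,,cation,1,,,michael_acceptor;quaternary_nitrogen;stilbene,low,4.8,"literature values (MW, logP, XLOGP3 max, LogS lower bound of reported range, BA, HBD, alerts, GI); hba and sa_score are synthetic stand-ins"
PFLID,629.73,5.23,8.61,-8.50,0.17,1,7,,zwitterion,2,4,3,quaternary_nitrogen,low,5.0,"literature values (MW, logP, WLOGP max, LogS lower bound of reported range, BA, rule violation counts, alert, GI); hbd/hba within-bounds and sa_score are synthetic stand-ins"
ICL,495,3.2,,-5.8,0.55,3,5,,neutral,0,,,,high,4.2,"literature values (MW as printed, approximate logP, BA, HBD, zero violations, no alerts, GI); log_s representative of reported '> -6', hba and sa_score synthetic stand-ins"
PFL,520,4.0,,-6.5,0.55,2,6,,neutral,1,,,,high,4.4,"literature values (MW, approximate logP, BA, one Lipinski violation, no alerts, GI); log_s midpoint of reported '-6 to -7', hbd/hba and sa_score synthetic stand-ins"
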