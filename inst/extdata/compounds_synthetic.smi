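# Parent and reference compound structures for exercising descriptor and
# alert computation. Melatonin, IC261 and PF-670462 are the well-known
# published structures; the three Nigella alkaloids carry the _synthetic
# suffix because they are plausible reconstructions of the published
# scaffold classes (piperidine-pyridone, indazole-carboxylic acid,
# indazole-phenol), not database downloads.
CC(=O)NCCc1c[nH]c2ccc(OC)cc12	melatonin
COc1cc(OC)c(/C=C2\C(=O)Nc3ccccc23)c(OC)c1	IC261
Nc1nccc(-c2n(C3CCCCC3)cnc2-c2ccc(F)cc2)n1	PF670462
O=C1C=CC=C(N2CCCCC2)N1	nigeglanine_synthetic
Cc1ccc2c(c1)nn(C)c2C(=O)O	nigellicine_synthetic
Oc1ccc(-c2nn(-c3ccccc3)c(C)c2C)cc1	nigellidine_synthetic
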