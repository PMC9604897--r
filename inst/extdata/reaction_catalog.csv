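"reaction","arm","annotation"
"re1","differentiation","OLYA6 (ostreolysin A6) transcription at the primordial stage; OLYA6 is the triggering point of fruiting"
"re2","differentiation","Translation of the OLYA6 transcript into Pleurotolysin, a MACPF-domain pore-forming protein"
"re3","differentiation","Pleurotolysin binds the membrane receptor (sphingomyelin/cholesterol recognition), switching cells from the vegetative to the reproductive phase"
"re4","differentiation","Differentiated hyphae aggregate into the dikaryotic mycelial knot"
"re5","pinhead","Fbh1 hydrophobin gene transcribed under high humidity"
"re6","pinhead","Conversion of mycelium aggregation to pinhead formation, catalysed by hydrophobin and inhibited by the Pofst protein, which limits excessive cluster formation"
"re7","pinhead","Translation of Fbh1 mRNA into hydrophobin, the surface-tension-lowering protein enabling aerial growth"
"re8","pinhead","Pofst (Pofst3) transcription; the gene controls sporocarp number and shape"
"re9","pinhead","Translation of Pofst mRNA; the Pofst protein inhibits cluster formation"
"re10","light_signaling","Blue light induces transcription of the PoWC1 photoreceptor gene"
"re11","light_signaling","Translation of PoWC1 mRNA into the White Collar 1 photoreceptor protein"
"re12","respiration","The PoWC1-FAD complex binds the GAPDH promoter and induces transcription; GAPDH is crucial in the glycolysis pathway"
"re13","biosynthesis","Couples the ATP development process and Laccase into assembly of the aggregate structural-protein pool feeding fruit-body conversion; PAL-derived phenolic precursors are important here, and a significant role is played by the PoWC1 output entering through the ATP branch"
"re14","respiration","Translation of GAPDH mRNA"
"re15","respiration","The PoWC1-FAD complex induces 6PGD transcription; 6PGD is rate-controlling in the pentose phosphate pathway"
"re16","differentiation","Conversion of pinhead to fruit body, the step involving most of the regulatory pathway; fuelled by ATP and the structural-protein pool"
"re17","respiration","The PoWC1-FAD complex induces PEPCK transcription; PEPCK is rate-controlling in gluconeogenesis"
"re18","respiration","Translation of PEPCK mRNA"
"re19","respiration","Phosphoenolpyruvate (PEP) formation from the sugar pool; both the G6PD and PFK enzymes are involved"
"re20","biosynthesis","DAHP synthase condenses PEP into the shikimic acid pathway"
"re21","respiration","PEP enters the TCA cycle in the mitochondria followed by the electron transport chain, generating ATP with reactive oxygen as a byproduct; GAPDH carries the glycolytic flux"
"re22","biosynthesis","PAL1 (phenylalanine ammonia-lyase) develops phenolic compounds via the phenylpropanoid pathway"
"re23","biosynthesis","PAL1 transcription; expression peaks in fruit gills"
"re24","biosynthesis","Translation of PAL1 mRNA"
"re25","lignin_degradation","PoLac12 laccase gene transcription; the laccase gene cluster is expressed across mycelium, primordium and fruit-body stages"
"re26","biosynthesis","PAL2 transcription; PAL2 is up-regulated during primordia, fruiting body and spore development"
"re27","biosynthesis","Translation of PAL2 mRNA"
"re28","biosynthesis","PAL2, with tyrosinases, drives pileus pigment formation"
"re29","differentiation","Membrane receptor synthesis (reconstruction filler)"
"re30","lignin_degradation","Formation of the mRNA-PoLac12 complex that carries out delignification"
"re31","lignin_degradation","The mRNA-PoLac12 complex, with laccases and carbohydrate-active enzymes (CAZymes), degrades substrate lignin into phenolic breakdown products and melanin-like pigments"
"re32","differentiation","Fruit body senescence and harvest (reconstruction filler)"
"re33","biosynthesis","DAHP synthase turnover (reconstruction filler)"
"re34","respiration","G6PD enzyme turnover (reconstruction filler)"
"re35","respiration","PFK enzyme turnover (reconstruction filler)"
"re36","differentiation","Life-cycle closure: mature fruit bodies shed spores whose germination seeds new dikaryotic mycelium"
"re37","light_signaling","PoWC1 binds the flavin chromophore FAD to form the PoWC1-FAD complex that activates respiratory enzyme expression"
"re38","differentiation","Membrane receptor internalization and turnover (reconstruction filler)"
"re39","respiration","PEPCK-dependent gluconeogenic energy supply feeding the ATP pool"
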