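# Published per-gene connection counts for the insecticide/cannabinoid
# seizure analysis: distinct insecticides, insecticide tetramers,
# cannabinoid tetramers and epilepsy-panel flag per gene, grouped by
# biological function.
pathway,gene_name,symbol,insecticide_count,insecticide_tetramers,cannabinoid_tetramers,epilepsy
Oxidation-reduction process,catalase,CAT,15,29,1,FALSE
Oxidation-reduction process,superoxide dismutase 2,SOD2,13,67,3,FALSE
Oxidation-reduction process,prostaglandin-endoperoxide synthase 2,PTGS2,9,42,5,FALSE
Oxidation-reduction process,cytochrome P450 family 11 subfamily A member 1,CYP11A1,7,15,0,FALSE
Oxidation-reduction process,nitric oxide synthase 2,NOS2,5,12,1,FALSE
Oxidation-reduction process,nitric oxide synthase 1,NOS1,2,6,1,FALSE
Oxidation-reduction process,peptidylglycine alpha-amidating monooxygenase,PAM,1,1,0,FALSE
Cholinergic signaling pathway,acetylcholinesterase,ACHE,7,10,0,FALSE
Cholinergic signaling pathway,cholinergic receptor nicotinic alpha 7 subunit,CHRNA7,4,15,0,FALSE
Cholinergic signaling pathway,cholinergic receptor muscarinic 1,CHRM1,3,5,0,FALSE
Cholinergic signaling pathway,cholinergic receptor nicotinic alpha 3 subunit,CHRNA3,3,3,0,FALSE
Cholinergic signaling pathway,cholinergic receptor nicotinic alpha 4 subunit,CHRNA4,3,6,0,TRUE
Cholinergic signaling pathway,choline O-acetyltransferase,CHAT,2,4,0,FALSE
Cholinergic signaling pathway,potassium voltage-gated channel subfamily Q member 1,KCNQ1,0,0,0,TRUE
Cholinergic signaling pathway,potassium voltage-gated channel subfamily Q member 2,KCNQ2,0,0,2,TRUE
Cholinergic signaling pathway,potassium voltage-gated channel subfamily Q member 3,KCNQ3,0,0,0,TRUE
Neuropeptide hormone activity,corticotropin releasing hormone,CRH,5,10,4,FALSE
Neuropeptide hormone activity,neuropeptide Y,NPY,3,5,0,FALSE
Neuropeptide hormone activity,adenylate cyclase activating polypeptide 1,ADCYAP1,2,5,0,FALSE
Neuropeptide hormone activity,cholecystokinin,CCK,2,6,1,FALSE
Neuropeptide hormone activity,oxytocin/neurophysin I prepropeptide,OXT,2,6,3,FALSE
Neuropeptide hormone activity,proopiomelanocortin,POMC,2,3,1,FALSE
Neuropeptide hormone activity,thyrotropin releasing hormone,TRH,1,2,0,FALSE
Dopaminergic signaling pathway,dopamine receptor D2,DRD2,4,25,2,FALSE
Dopaminergic signaling pathway,dopamine receptor D1,DRD1,3,13,3,FALSE
Dopaminergic signaling pathway,dopamine receptor D3,DRD3,1,1,0,FALSE
Dopaminergic signaling pathway,glutamate ionotropic receptor NMDA type subunit 2A,GRIN2A,0,0,0,TRUE
Dopaminergic signaling pathway,glutamate ionotropic receptor NMDA type subunit 2B,GRIN2B,0,0,0,TRUE
Dopaminergic signaling pathway,sodium voltage-gated channel alpha subunit 1,SCN1A,0,0,0,TRUE
Retrograde endocannabinoid signaling pathway,fatty acid amide hydrolase,FAAH,3,4,0,FALSE
Retrograde endocannabinoid signaling pathway,cannabinoid receptor 1,CNR1,2,2,2,FALSE
Retrograde endocannabinoid signaling pathway,gamma-aminobutyric acid type A receptor subunit alpha1,GABRA1,0,0,0,TRUE
Retrograde endocannabinoid signaling pathway,gamma-aminobutyric acid type A receptor subunit beta3,GABRB3,0,0,0,TRUE
Retrograde endocannabinoid signaling pathway,gamma-aminobutyric acid type A receptor subunit gamma2,GABRG2,0,0,0,TRUE
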