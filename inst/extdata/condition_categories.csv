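# Editable qualifying-condition category map, seeded from the category
# scheme used in U.S. medical-cannabis condition surveys (each category
# belongs to exactly one domain: neurological, psychological or
# pain-and-injury).  Condition names are normalized (lower case, no
# punctuation) before matching.
condition,category,domain
epilepsy,Movement Disorders,neurological
seizures,Movement Disorders,neurological
seizure disorders,Movement Disorders,neurological
multiple sclerosis,Movement Disorders,neurological
severe or persistent muscle spasms,Movement Disorders,neurological
spasticity,Movement Disorders,neurological
parkinson s disease,Movement Disorders,neurological
huntington s disease,Movement Disorders,neurological
tourette syndrome,Movement Disorders,neurological
amyotrophic lateral sclerosis,Neurodegenerative Conditions,neurological
alzheimer s disease,Neurodegenerative Conditions,neurological
dementia,Neurodegenerative Conditions,neurological
traumatic brain injury,Other Neurological Conditions,neurological
neuropathy,Other Neurological Conditions,neurological
migraine,Other Neurological Conditions,neurological
cachexia,Anorexia and Weight Loss,neurological
wasting syndrome,Anorexia and Weight Loss,neurological
anorexia,Anorexia and Weight Loss,neurological
post traumatic stress disorder,Psychiatric Conditions,psychological
anxiety,Psychiatric Conditions,psychological
autism spectrum disorder,Psychiatric Conditions,psychological
opioid use disorder,Psychiatric Conditions,psychological
chronic pain,Pain-Related Conditions,pain-and-injury
severe pain,Pain-Related Conditions,pain-and-injury
intractable pain,Pain-Related Conditions,pain-and-injury
arthritis,Pain-Related Conditions,pain-and-injury
fibromyalgia,Pain-Related Conditions,pain-and-injury
sickle cell disease,Pain-Related Conditions,pain-and-injury
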