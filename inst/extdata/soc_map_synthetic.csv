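pt,soc,is_primary
death,General disorders and administration site conditions,TRUE
condition aggravated,General disorders and administration site conditions,TRUE
disease progression,General disorders and administration site conditions,TRUE
treatment failure,General disorders and administration site conditions,TRUE
therapy non-responder,General disorders and administration site conditions,TRUE
multiple organ dysfunction syndrome,General disorders and administration site conditions,TRUE
general physical health deterioration,General disorders and administration site conditions,TRUE
drug interaction,General disorders and administration site conditions,TRUE
drug resistance,Infections and infestations,TRUE
hallucination,Psychiatric disorders,TRUE
hallucination visual,Psychiatric disorders,TRUE
delirium,Psychiatric disorders,TRUE
confusional state,Psychiatric disorders,TRUE
photosensitivity reaction,Skin and subcutaneous tissue disorders,TRUE
actinic keratosis,Skin and subcutaneous tissue disorders,TRUE
visual impairment,Eye disorders,TRUE
vision blurred,Eye disorders,TRUE
drug level increased,Investigations,TRUE
drug level decreased,Investigations,TRUE
drug level below therapeutic,Investigations,TRUE
antibiotic level below therapeutic,Investigations,TRUE
liver function test abnormal,Investigations,TRUE
hepatic enzyme increased,Investigations,TRUE
electrocardiogram qt prolonged,Investigations,TRUE
blood creatinine increased,Investigations,TRUE
respiratory failure,"Respiratory, thoracic and mediastinal disorders",TRUE
hepatic function abnormal,Hepatobiliary disorders,TRUE
hepatotoxicity,Hepatobiliary disorders,TRUE
drug-induced liver injury,Hepatobiliary disorders,TRUE
hepatocellular injury,Hepatobiliary disorders,TRUE
cholestasis,Hepatobiliary disorders,TRUE
neurotoxicity,Nervous system disorders,TRUE
neuropathy peripheral,Nervous system disorders,TRUE
nervous system disorder,Nervous system disorders,TRUE
hypokalaemia,Metabolism and nutrition disorders,TRUE
pseudoaldosteronism,Endocrine disorders,TRUE
febrile neutropenia,Blood and lymphatic system disorders,TRUE
neutropenia,Blood and lymphatic system disorders,TRUE
thrombocytopenia,Blood and lymphatic system disorders,TRUE
pancytopenia,Blood and lymphatic system disorders,TRUE
eosinophilia,Blood and lymphatic system disorders,TRUE
cardiac arrest,Cardiac disorders,TRUE
product use issue,Product issues,TRUE
off label use,Product issues,TRUE
underdose,Product issues,TRUE
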