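# toy symptom/treatment keyphrase lexicon
fever	symptom
sore throat	symptom
red eye	symptom
cough	symptom
runny nose	symptom
headache	symptom
sneezing	symptom
itchy eyes	symptom
eye drops	treatment
antibiotics	treatment
cough syrup	treatment
nasal spray	treatment
allergy meds	treatment
flu shot	treatment
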