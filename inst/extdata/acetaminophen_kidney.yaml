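drug: acetaminophen
synonyms:
- ACETAMINOPHEN
- PARACETAMOL
- TYLENOL
- PANADOL
- APAP
- OFIRMEV
- CALPOL
- DOLIPRANE
- EFFERALGAN
- PERFALGAN
target_pts:
- pt: Acute kidney injury
  code: '10069339'
- pt: Subacute kidney injury
  code: '10081980'
- pt: Acute prerenal failure
  code: '10001017'
- pt: Renal failure acute ischemic
  code: '10038439'
- pt: Blood creatinine increased
  code: '10005483'
- pt: Blood urea abnormal
  code: '10005846'
- pt: Glomerular filtration rate decreased
  code: '10018358'
- pt: Renal impairment
  code: '10062237'
- pt: Oliguria
  code: '10030302'
- pt: Anuria
  code: '10002847'
- pt: Dialysis
  code: '10061105'
- pt: Proteinuria
  code: '10037032'
- pt: Nephrosis osmotic
  code: '10029163'
- pt: Renal tubular injury
  code: '10078933'
- pt: Nephropathy toxic
  code: '10029155'
- pt: Nephritis allergic
  code: '10029120'
- pt: Tubulointerstitial nephritis
  code: '10048302'
window:
- '2004-01-01'
- '2021-03-31'
suicide_terms:
- intentional overdose
- poisoning deliberate
- suicidal ideation
- suicide attempt
- intentional product misuse
- overdose
suicide_dose_threshold_g: 12.0
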