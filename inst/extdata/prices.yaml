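drug_prices:
  TDF/FTC: 10.54
  AZT/3TC: 8.41
  ABC/3TC: 18.64
  d4T/3TC: 3.01
  NVP: 2.34
  EFV: 4.26
  LPV/r: 36.7
  CTX: 0.93
cpi_series:
  '2008': 78.9
  '2009': 89.4
  '2010': 92.5
  '2011': 100.0
exchange_rate: 4861.0
reference_year: 2011
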