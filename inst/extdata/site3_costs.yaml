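site_id: site3
currency: ZMK
capital_items:
- item: buildings
  replacement_cost: 1.3724351e+09
  life_years: 50.0
  year: 2010.0
- item: equipment
  replacement_cost: 1.0563601e+08
  life_years: 5.0
  year: 2011.0
support_staff:
- role: art_clinic_support
  annual_salary_allowances: 5.7665265e+07
  art_fraction: 0.6
  year: 2011.0
n_art_patients: 1167.0
n_nonart_patients: 934.0
visits_per_year_art: 8.0
visits_per_year_nonart: 4.0
provider_costs:
- provider_type: doctor_or_clinical_officer
  consultations_per_year: 7002.0
  art_fraction: 0.65
  year: 2011.0
  annual_cost: 2.9847587e+07
- provider_type: nurse
  consultations_per_year: 8169.0
  art_fraction: 0.65
  year: 2011.0
  annual_cost: 2.9323945e+07
- provider_type: counselor
  consultations_per_year: 9336.0
  art_fraction: 0.65
  year: 2011.0
  annual_cost: 2.1643864e+07
- provider_type: pharmacist
  consultations_per_year: 10503.0
  art_fraction: 0.65
  year: 2011.0
  annual_cost: 2.2778422e+07
lab_inputs:
- test_code: cd4
  reagent_consumable_cost_per_test: 34707.54
  annual_equipment_labor_space: 4.049213e+07
  tests_per_year: 1750.0
  year: 2011.0
- test_code: blood_chemistry
  reagent_consumable_cost_per_test: 14612.166
  annual_equipment_labor_space: 1.2508014e+07
  tests_per_year: 1284.0
  year: 2011.0
- test_code: full_blood_count
  reagent_consumable_cost_per_test: 6241.524
  annual_equipment_labor_space: 6312261.272
  tests_per_year: 1517.0
  year: 2011.0
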