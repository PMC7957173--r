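# FLAURA: osimertinib vs first-generation EGFR-TKI, 21-day cycles
trial: FLAURA
cycle_days: 21
horizon_years: 5
discount_annual: 0.03
patient: {height_m: 1.64, weight_kg: 65.0, bsa_m2: 1.72}
wtp: 30828
psa_iterations: 1000
seed: 1
dsa_cost_range: 0.30
dsa_other_range: 0.20
drug_prices:
  osimertinib: {pack_price: 2171.48, pack_content_mg: 2400}  # 80 mg * 30
  gefitinib: {pack_price: 22.65, pack_content_mg: 250}       # 0.25 g * 1
fixed_costs:
  follow_up_per_cycle: 55.60
  supportive_care_per_cycle: 337.50
  ae_cost_per_cycle: 507.40
  pd_cost_per_week: 276.75
  terminal_care_per_week: 1412.92
  examination_per_cycle: 0
arms:
  - name: osimertinib
    role: treatment
    route: oral_only
    pfs_median_months: 18.9
    os_median_months: 38.6
    utilities:
      pfs_on_treatment: 0.8400
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.34
    regimen:
      - {drug: osimertinib, dosing: fixed_daily, dose: 80}
  - name: egfr_tki  # gefitinib or erlotinib; priced as gefitinib
    role: control
    route: oral_only
    pfs_median_months: 10.2
    os_median_months: 31.8
    utilities:
      pfs_on_treatment: 0.8050  # first-generation TKI
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.45
    regimen:
      - {drug: gefitinib, dosing: fixed_daily, dose: 250}
metadata:
  exchange_rate_cny_per_usd: 7.0459
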