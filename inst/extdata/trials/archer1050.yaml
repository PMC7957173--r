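# ARCHER 1050: dacomitinib vs gefitinib, 28-day cycles
trial: ARCHER 1050
cycle_days: 28
horizon_years: 5
discount_annual: 0.03
patient: {height_m: 1.64, weight_kg: 65.0, bsa_m2: 1.72}
wtp: 30828
psa_iterations: 1000
seed: 1
dsa_cost_range: 0.30
dsa_other_range: 0.20
drug_prices:
  dacomitinib: {pack_price: 803.30, pack_content_mg: 450}  # 15 mg * 30
  gefitinib: {pack_price: 22.65, pack_content_mg: 250}     # 0.25 g * 1
fixed_costs:
  follow_up_per_cycle: 55.60
  supportive_care_per_cycle: 337.50
  ae_cost_per_cycle: 507.40
  pd_cost_per_week: 276.75
  terminal_care_per_week: 1412.92
  examination_per_cycle: 0
arms:
  - name: dacomitinib
    role: treatment
    route: oral_only
    pfs_median_months: 14.7
    os_median_months: 34.1
    utilities:
      pfs_on_treatment: 0.8270
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.63
    regimen:
      - {drug: dacomitinib, dosing: fixed_daily, dose: 45}
  - name: gefitinib
    role: control
    route: oral_only
    pfs_median_months: 9.2
    os_median_months: 26.8
    utilities:
      pfs_on_treatment: 0.8000
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.41
    regimen:
      - {drug: gefitinib, dosing: fixed_daily, dose: 250}
metadata:
  exchange_rate_cny_per_usd: 7.0459
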