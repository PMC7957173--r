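# NEJ026: bevacizumab + erlotinib vs erlotinib, 21-day cycles
trial: NEJ026
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
  bevacizumab: {pack_price: 212.89, pack_content_mg: 100}
  erlotinib: {pack_price: 10.08, pack_content_mg: 150}
fixed_costs:
  follow_up_per_cycle: 55.60
  supportive_care_per_cycle: 337.50
  ae_cost_per_cycle: 507.40
  pd_cost_per_week: 276.75
  terminal_care_per_week: 1412.92
  examination_per_cycle: 0
arms:
  - name: bev_erlotinib
    role: treatment
    route: contains_iv
    pfs_median_months: 16.9
    os_median_months: 50.7
    utilities:
      pfs_on_treatment: 0.7600
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.88
    regimen:
      - {drug: bevacizumab, dosing: per_kg, dose: 15}
      - {drug: erlotinib, dosing: fixed_daily, dose: 150}
  - name: erlotinib
    role: control
    route: oral_only
    pfs_median_months: 13.3
    os_median_months: 46.2
    utilities:
      pfs_on_treatment: 0.8100
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.46
    regimen:
      - {drug: erlotinib, dosing: fixed_daily, dose: 150}
metadata:
  exchange_rate_cny_per_usd: 7.0459
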