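# NCT02148380: pemetrexed + carboplatin + gefitinib vs chemotherapy vs
# gefitinib, 28-day cycles. In the combination arm gefitinib is dosed
# d5-21 (17 of 28 days) during the first 6 cycles, then daily in
# maintenance alongside pemetrexed.
trial: NCT02148380
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
  gefitinib: {pack_price: 22.65, pack_content_mg: 250}
  carboplatin: {pack_price: 7.34, pack_content_mg: 100}
  pemetrexed: {pack_price: 190.61, pack_content_mg: 200}
fixed_costs:
  follow_up_per_cycle: 55.60
  supportive_care_per_cycle: 337.50
  ae_cost_per_cycle: 507.40
  pd_cost_per_week: 276.75
  terminal_care_per_week: 1412.92
  examination_per_cycle: 0
arms:
  - name: pem_carbo_gef
    role: treatment
    route: contains_iv
    pfs_median_months: 17.5
    os_median_months: 32.6
    utilities:
      pfs_on_treatment: 0.7600
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.375
    regimen:
      - {drug: pemetrexed, dosing: per_bsa, dose: 500}
      - {drug: carboplatin, dosing: auc_dose, dose: 500, max_cycles: 6}
      - {drug: gefitinib, dosing: fixed_daily, dose: 250, days_on_per_cycle: 17,
         max_cycles: 6, maintenance: true, maintenance_days_on: 28}
  - name: pem_carbo
    role: other  # chemotherapy comparator
    route: contains_iv
    pfs_median_months: 5.7
    os_median_months: 24.3
    utilities:
      pfs_on_treatment: 0.7600
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.175
    regimen:
      - {drug: pemetrexed, dosing: per_bsa, dose: 500}
      - {drug: carboplatin, dosing: auc_dose, dose: 500, max_cycles: 6}
  - name: gefitinib
    role: control
    route: oral_only
    pfs_median_months: 11.9
    os_median_months: 25.8
    utilities:
      pfs_on_treatment: 0.8000
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.122
    regimen:
      - {drug: gefitinib, dosing: fixed_daily, dose: 250}
metadata:
  exchange_rate_cny_per_usd: 7.0459
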