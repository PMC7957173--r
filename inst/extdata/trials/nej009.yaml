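# NEJ009: gefitinib + carboplatin + pemetrexed vs gefitinib, 21-day cycles.
# Platinum doublet capped at 6 cycles, then maintenance pemetrexed + gefitinib.
trial: NEJ009
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
  gefitinib: {pack_price: 22.65, pack_content_mg: 250}
  carboplatin: {pack_price: 7.34, pack_content_mg: 100}
  pemetrexed: {pack_price: 190.61, pack_content_mg: 200}  # 0.2 g * 1
fixed_costs:
  follow_up_per_cycle: 55.60
  supportive_care_per_cycle: 337.50
  ae_cost_per_cycle: 507.40
  pd_cost_per_week: 276.75
  terminal_care_per_week: 1412.92
  examination_per_cycle: 0
arms:
  - name: gef_carbo_pem
    role: treatment
    route: contains_iv
    pfs_median_months: 20.9
    os_median_months: 50.9
    utilities:
      pfs_on_treatment: 0.7600
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.653
    regimen:
      - {drug: pemetrexed, dosing: per_bsa, dose: 500}          # d1, continues in maintenance
      # AUC 5 mg-equivalent: no GFR published; 500 mg per administration assumed
      - {drug: carboplatin, dosing: auc_dose, dose: 500, max_cycles: 6}
      - {drug: gefitinib, dosing: fixed_daily, dose: 250}
  - name: gefitinib
    role: control
    route: oral_only
    pfs_median_months: 11.9
    os_median_months: 38.8
    utilities:
      pfs_on_treatment: 0.8000
      pd: 0.7000
      ae_disutility: -0.0731
      ae_rate_grade3plus: 0.31
    regimen:
      - {drug: gefitinib, dosing: fixed_daily, dose: 250}
metadata:
  exchange_rate_cny_per_usd: 7.0459
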