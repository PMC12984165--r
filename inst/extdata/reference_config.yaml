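schema_version: '1.0'
strategies:
- name: conventional
  sensitivity: 0.691
  specificity: 0.954
  cost_per_scan: 110.0
- name: companion
  sensitivity: 0.715
  specificity: 0.968
  cost_per_scan: 97.5
- name: standalone
  sensitivity: 0.805
  specificity: 0.893
  cost_per_scan: 80.0
policy:
  start_age: 50.0
  stop_age: 69.0
  interval: 2.0
  compliance: 0.4
  horizon: 50.0
  cohort_size: 10000.0
  attendance_model: independent
  half_cycle: no
economics:
  discount_rate: 0.03
  wtp_threshold: 50000.0
  currency_year: 2023.0
natural_history:
  ages:
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  onset_rate:
  - 0.000605439667
  - 0.000668100416
  - 0.000735255039
  - 0.000806824264
  - 0.000882644916
  - 0.000962463902
  - 0.001045935406
  - 0.001132622006
  - 0.0012220002
  - 0.001313470497
  - 0.00140637188
  - 0.0015
  - 0.00159362812
  - 0.001686529503
  - 0.0017779998
  - 0.001867377994
  - 0.001954064594
  - 0.002037536098
  - 0.002117355084
  - 0.002193175736
  - 0.002264744961
  - 0.002331899584
  - 0.002394560333
  - 0.002452723429
  - 0.002506450611
  - 0.002555858406
  - 0.002601107279
  - 0.002642391234
  - 0.002679928218
  - 0.002713951605
  - 0.002744702865
  - 0.00277242546
  - 0.002797359927
  - 0.002819740049
  - 0.002839790011
  - 0.00285772238
  - 0.002873736816
  - 0.002888019338
  - 0.002900742065
  - 0.002912063308
  - 0.002922127928
  - 0.00293106789
  - 0.00293900294
  - 0.00294604137
  - 0.002952280825
  - 0.002957809119
  - 0.002962705047
  - 0.002967039172
  - 0.002970874571
  - 0.002974267544
  - 0.002977268276
  - 0.002979921447
  other_cause_mortality:
  - 0.001757604358
  - 0.002023215701
  - 0.00222858518
  - 0.002429977815
  - 0.002687667314
  - 0.0027980626
  - 0.003113939408
  - 0.003263013647
  - 0.003531370317
  - 0.003703625006
  - 0.00446006796
  - 0.004624845867
  - 0.005257562801
  - 0.005279092172
  - 0.006058683535
  - 0.006368693707
  - 0.006946310765
  - 0.007841836614
  - 0.00822313392
  - 0.008880716353
  - 0.01011784074
  - 0.011126859138
  - 0.012136383289
  - 0.013109203187
  - 0.014580837884
  - 0.015783251253
  - 0.015907091024
  - 0.018164018316
  - 0.020260719408
  - 0.021430904107
  - 0.022977824739
  - 0.025606064887
  - 0.028328935699
  - 0.030408367954
  - 0.034052274242
  - 0.036872119946
  - 0.040043771412
  - 0.042818990063
  - 0.044887569579
  - 0.053442579495
  - 0.053442579495
  - 0.060009400425
  - 0.064389238433
  - 0.070609341184
  - 0.074966056039
  - 0.088181197575
  - 0.09302655833
  - 0.102832419101
  - 0.114243823001
  - 0.121346333214
  - 0.130570678284
  - 0.140935247174
  stage_progression:
  - 0.5
  - 0.5
  - 0.666666666667
  - 0.8
  - 0.0
  clinical_detection:
  - 0.05
  - 0.12
  - 0.25
  - 0.5
  - 0.8
  recurrence_rate:
  - 0.005
  - 0.01
  - 0.03
  - 0.06
  - 0.1
  bc_mortality:
  - 0.001
  - 0.005
  - 0.02
  - 0.08
  - 0.3
  bc_mortality_recurrence: 0.25
costs:
  treatment_cost:
  - 20000.0
  - 30000.0
  - 45000.0
  - 67500.0
  - 101250.0
  remission_fraction: 0.05
  recurrence_cost: 40000.0
  ultrasound_cost: 180.0
  biopsy_cost: 800.0
  biopsy_fraction_of_recalls: 0.5
  mammogram_base_cost: 110.0
  radiologist_read_fee: 17.5
  ai_fee: 5.0
utilities:
  healthy: 0.92
  undiagnosed: 0.9
  by_stage:
  - 0.86
  - 0.82
  - 0.75
  - 0.62
  - 0.48
  remission: 0.84
  recurrence: 0.6
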