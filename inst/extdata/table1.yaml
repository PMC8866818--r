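sources:
  dataset1:
    pd:
      'n': 29.0
      moca_mean: 25.0
      moca_sd: 3.0
      fluency_mean: 16.0
      fluency_sd: 4.0
      female_fraction: 0.28
      age_mean: 67.1
      age_sd: 8.0
      education_mean: 17.9
      education_sd: 2.5
      hy_mean: 2.29
      hy_sd: 0.5
      volume_mean: 3700.0
      volume_sd: 400.0
      icv_mean: 1450000.0
      icv_sd: 130000.0
      n_below: ~
    hc:
      'n': 21.0
      moca_mean: 26.6
      moca_sd: 3.0
      fluency_mean: 20.0
      fluency_sd: 4.0
      female_fraction: 0.62
      age_mean: 69.7
      age_sd: 8.0
      education_mean: 17.1
      education_sd: 2.5
      hy_mean: 0.0
      hy_sd: 0.0
      volume_mean: 3700.0
      volume_sd: 400.0
      icv_mean: 1450000.0
      icv_sd: 130000.0
      n_below: ~
  dataset2:
    pd:
      'n': 69.0
      moca_mean: 26.9
      moca_sd: 3.0
      fluency_mean: 16.0
      fluency_sd: 4.0
      female_fraction: 0.34
      age_mean: 61.8
      age_sd: 8.0
      education_mean: 16.4
      education_sd: 2.5
      hy_mean: 1.65
      hy_sd: 0.5
      volume_mean: 3700.0
      volume_sd: 400.0
      icv_mean: 1450000.0
      icv_sd: 130000.0
      n_below: ~
    hc:
      'n': 31.0
      moca_mean: 28.1
      moca_sd: 3.0
      fluency_mean: 20.0
      fluency_sd: 4.0
      female_fraction: 0.39
      age_mean: 58.7
      age_sd: 8.0
      education_mean: 17.2
      education_sd: 2.5
      hy_mean: 0.0
      hy_sd: 0.0
      volume_mean: 3700.0
      volume_sd: 400.0
      icv_mean: 1450000.0
      icv_sd: 130000.0
      n_below: ~
planted_effect_delta: 0.8
threshold: 26.0
seed: 1
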