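version: '1.0'
ligands:
  egf:
    mw_kda: 6.4
    kon_s_per_nm_min: 0.097
    koff_s_per_min: 0.24
    kon_e_per_nm_min: 0.097
    koff_e_per_min: 2.0
  hrg:
    mw_kda: 7.5
    kon_s_per_nm_min: 0.06
    koff_s_per_min: 0.12
    kon_e_per_nm_min: 0.097
    koff_e_per_min: 2.0
rates:
  kc_s_per_cell_min: 0.0001
  kc_e_per_cell_min: 0.0001
  ee_volume_factor: 1.0
  affinity_fold:
    r12_egf: 1.6
    r23_hrg: 25.0
    r13_hrg_egf: 3.0
  ku_per_min:
    ku11es: 0.6
    ku11ees: 0.3
    ku12es: 1.0
    ku13es: 0.5
    ku13hs: 0.4
    ku13ehs: 0.1
    ku22s: 10.0
    ku23hs: 0.05
    ku33hs: 2.0
    ku33hhs: 1.0
    ku11ei: 1.2
    ku11eei: 0.6
    ku12ei: 2.0
    ku13ei: 1.0
    ku13hi: 0.8
    ku13ehi: 0.2
    ku22i: 20.0
    ku23hi: 0.1
    ku33hi: 4.0
    ku33hhi: 2.0
pf:
  pf11es: 0.015
  pf11ees: 0.03
  pf12es: 0.45
  pf13es: 0.02
  pf13hs: 0.02
  pf13ehs: 0.03
  pf21es: 0.2
  pf22s: 0.01
  pf23hs: 0.15
  pf32hs: 0.1
  pf31es: 0.05
  pf31hs: 0.05
  pf31ehs: 0.08
  pf11ei: 0.01
  pf11eei: 0.02
  pf12ei: 0.05
  pf13ei: 0.01
  pf13hi: 0.01
  pf13ehi: 0.015
  pf21ei: 0.1
  pf22i: 0.005
  pf23hi: 0.08
  pf32hi: 0.05
  pf31ei: 0.025
  pf31hi: 0.025
  pf31ehi: 0.04
trafficking:
  delta1: 2.0
  her1:
    kt_per_min: 0.02
    ke_per_min: 0.2
    kx_per_min: 0.15
    f: 0.5
  her23:
    kt_per_min: 0.01
    ke_per_min: 0.03
    kx_per_min: 0.15
    f: 0.85
expression:
  parental:
    her1: 200000.0
    her2: 2000.0
    her3: 2000.0
  24H:
    her1: 200000.0
    her2: 600000.0
    her3: 2000.0
  B5:
    her1: 200000.0
    her2: 2000.0
    her3: 40000.0
  D20:
    her1: 200000.0
    her2: 600000.0
    her3: 40000.0
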