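Package: herdimer
Title: Mechanistic Modelling of HER1/HER2/HER3 Dimerization, Activation and Trafficking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mass-action ordinary differential equation model of the HER/ErbB
    receptor network in cells co-expressing EGFR (HER1), HER2 and HER3.  The
    model couples EGF and heregulin binding, combinatorial receptor
    dimerization, lumped phosphorylation-efficiency (pf) readouts and
    three-compartment trafficking (cell surface, early and late endosomes) to
    predict ELISA-style observables: total phospho-receptor, internal
    phospho-receptor and receptor mass.  The package provides the network
    assembly, a compiled right-hand side, pre-stimulation equilibration, an
    in-silico pertuzumab (2C4) HER2-blocking mode, a synthetic-data generator
    emulating the dose-response and time-course ELISA design, progressive
    multistart nonlinear least-squares parameter estimation with k-means
    solution clustering, per-dimer phosphorylation decomposition, expression
    grid scans, and multilinear regression linking Erk/Akt activation to
    receptor- or dimer-level phosphorylation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
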