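Package: aquatraj
Title: Structure, Hydrogen Bonding, and Dynamics of Liquid Water from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of water in
    cubic periodic boxes. Computes radial distribution functions with
    spline-interpolated first-shell descriptors and coordination numbers,
    counts hydrogen bonds with a smoothed two-switching-function geometric
    criterion, estimates self-diffusion coefficients from the Einstein
    relation with the hydrodynamic finite-size correction for cubic cells,
    fits orientational relaxation times from Legendre autocorrelation
    functions, and estimates the equilibrium density from energy-versus-volume
    scans around trajectory snapshots. Includes a reversible multiple-time-step
    (r-RESPA) velocity-Verlet integrator with pluggable force providers, and
    synthetic-trajectory generators (Brownian translation, isotropic rotational
    diffusion, proton-disordered cubic ice obeying the Bernal-Fowler rules,
    ideal-gas configurations, water dimers) with known ground truth so every
    analysis stage can be validated without an electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    generics,
    ggplot2,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
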