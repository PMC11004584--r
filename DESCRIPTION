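Package: kleptodyn
Title: Dynamics of a Two-Predator-One-Prey Model with Kleptoparasitism
    and Counter-Attack
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full dynamical analysis of a three-species food-web
    model in which a second predator steals part of the first predator's kills
    (kleptoparasitism) and the host predator retaliates. Provides the
    dimensional and nondimensional vector fields and their exact Jacobian,
    closed-form boundary equilibria and two independent routes to the interior
    (coexistence) equilibria, Routh-Hurwitz and eigenvalue stability reports,
    Lyapunov-function certificates for global stability, stiff-capable
    simulation with positivity and boundedness monitors and attractor
    classification, one-parameter equilibrium continuation with fold,
    transcritical (Sotomayor) and Hopf (Liu criterion) detection, Hopf
    normal-form coefficients (first and second Lyapunov coefficients) via a
    center-manifold reduction, and two-parameter Hopf-curve continuation with
    Bautin (generalized Hopf) point location.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
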