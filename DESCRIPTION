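Package: dyadgame
Title: Feedback Nash Equilibria of Dyadic Relationship Effort Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Solves one- and two-player infinite-horizon discounted
    differential games describing long-term effort control of a dyadic
    relationship ("love games"). The feeling state decays linearly and is
    sustained by costly effort; stationary feedback Nash equilibria are
    computed from the coupled Hamilton-Jacobi-Bellman system by a
    semi-Lagrangian discretization with mesh-free radial-basis-function
    collocation and a double loop of value and game iteration. Includes
    closed-loop trajectory and shock-stabilization simulators with
    discounted well-being accounting and recovery-time measurement, an
    independent Pontryagin saddle-path oracle for the one-dimensional
    problem (closed-form equilibrium, saddle classification, stable-manifold
    shooting), and config-driven experiment runners producing CSV/JSON
    artifacts for feedback curves, heterogamy sweeps and recovery tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
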