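Package: omnisim
Title: Mechanistic Simulation of Quantitative Traits from Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("omnisim", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates quantitative traits mechanistically under the omnigenic
    model. Grows scale-free regulatory-network geometries as d-dimensional
    simplicial complexes, maps SNP polymorphism into per-genotype
    transcription rates through a relative marker-effect matrix, integrates
    coupled mRNA/protein dynamics under a statistical-thermodynamic model of
    RNA polymerase II promoter binding (stochastic Euler-Maruyama or
    delay-differential Runge-Kutta modes), and assembles trait values as
    weighted sums of normalized core-gene products. Includes
    gene-by-gene (kappa) and gene-by-environment (phi) response studies,
    connectivity diagnostics with discrete power-law fits, and a deterministic
    parallel pipeline driven by plain-text configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
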