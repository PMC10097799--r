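Package: tendonheal
Title: Mechanoregulated Tissue Differentiation During Tendon Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative mechanobiological simulation of Achilles tendon healing
    on an idealized stump-callus geometry. Each simulated day a quasi-static
    tensile load is solved on a finite element mesh, biophysical stimuli
    (principal strains, octahedral shear strain, hydrostatic stress, pore
    pressure, fluid flow) are extracted, nodal cell, angiogenesis and oxygen
    fields evolve by implicit diffusion with strain-gated vessel growth and
    cellular oxygen consumption, and declarative mechanoregulatory rule sets
    (principal strain, Carter-type, Claes-Heigele-type, Prendergast-type, and
    an oxygen/angiogenesis-coupled scheme) select the tissue produced in every
    callus element. Tissue densities feed back into the material model through
    a linear mixture rule, collagen fibrils reorient toward the maximum
    principal strain, and an endochondral gate can restrict bone formation to
    a cartilage intermediate. Summaries include construct stiffness at load,
    callus bone volume, temporal density curves and VTK field exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
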