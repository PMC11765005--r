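Package: lietrack
Title: Lie-Group World Models and World-Tracking Neural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and audit tools for agents that track structured
    sensory streams generated by matrix Lie groups. Provides generator
    bases and exponential maps for planar and spatial transformation
    groups, product-of-exponentials kinematic chains rendered to images
    by a differentiable Gaussian-splat camera, a reservoir-based
    recurrent agent whose readout is constrained to match its input
    stream (a world-tracking differential-algebraic system) with
    proportional error feedback monitored by a Lyapunov function,
    layer-wise invariance and equivariance audits of feedforward
    networks under infinitesimal group actions, and post-hoc analyses
    of conserved readout quantities, trajectory-manifold effective
    dimensionality, and hierarchical nested constraint manifolds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    optparse,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
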