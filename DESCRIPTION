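Package: tracerval
Title: Validation of Diffusion Tractography Against Tracer Histology on
    Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds density distribution maps (DDMs) of tracer-labeled fibers
    and diffusion-tensor tractography streamlines on the white/gray matter
    interface and quantifies their inter-regional and voxelwise agreement.
    Provides a synthetic phantom generator (tissue labels, tensor fields with
    curved and crossing bundles, Rician-noise diffusion-weighted signal,
    ground-truth fiber and soma counts, synthetic micrographs, invertible
    deformation fields with analytic Jacobians), log-linear diffusion tensor
    fitting with principal-direction-preserving reorientation, deterministic
    (FACT) and probabilistic streamline tracking with seed-depth extension,
    a micrograph fiber-segmentation pipeline, thin-plate-spline landmark
    registration, Jacobian-compensated density transfer between spaces,
    interface projection, and the regional/voxelwise correlation statistics
    used to compare histological and tractographic connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    igraph,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
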