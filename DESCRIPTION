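Package: nfflux
Title: Nerve Fiber Flux Analysis for Wide-Field Peripapillary OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal nerve fibers over their arcuate courses from
    wide-field peripapillary optical coherence tomography (OCT) nerve fiber
    layer (NFL) thickness maps. Implements a flux-conservation tracing
    algorithm that divides the peripapillary NFL into 64 equal-flux tracks,
    iteratively recovers nerve fiber trajectories constrained to an arcuate
    model, compensates for fiber origination on macular retinal ganglion
    cells, averages healthy-eye trajectories into a normative template, and
    quantifies nerve fiber flux (NFF) per track and per visual-field
    corresponding sector with deviation maps and normative classification.
    Includes a synthetic-eye generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
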