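Package: v2pool
Title: Feedforward Pooling Models of V2 Receptive Fields from V1 Inputs
Version: 0.1.0
Authors@R:
    person("V2Pool", "Developers", email = "v2pool@example.org", role = c("aut", "cre"))
Description: Tools for deriving secondary visual cortex (V2) receptive fields
    from anatomically identified primary visual cortex (V1) inputs. Implements
    processing of intrinsic-signal optical-imaging orientation maps (single
    condition maps, pixelwise vector-sum preferred orientations, von Mises
    tuning fits), cortex-to-visual-field mapping by elliptic grid generation,
    circular statistics and resampling nulls for the orientation bias of
    labeled inputs, a linear feedforward Gabor-pooling model of V2 responses
    with eight-fold leave-one-out validation, and modulation-index analysis of
    responses to naturalistic textures versus spectrally matched noise. A
    synthetic-data generator with known ground truth supports end-to-end
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
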