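Package: daltonize
Title: Achromatic Contrast-Preserving Daltonization for Dichromat Viewers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recolors sRGB images for protan and deutan dichromat observers by
    modulating only the per-pixel achromatic component: a scalar weight mask is
    optimized so that local color contrasts lost under linear dichromacy
    simulation are restored as lightness contrasts, while the chromaticity of
    every pixel is left untouched. Includes the Vienot linear simulation of
    protanopia and deuteranopia, structure-tensor local-contrast diagnostics,
    gradient-domain reconstruction of the weight mask, quantile tone mapping,
    objective evaluation metrics (RMS local contrast, chromatic difference in
    CIELAB and in proLab chromaticity coordinates), and generators for
    synthetic confusion-contrast test images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
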