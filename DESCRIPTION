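Package: colorgamut
Title: Opponent-Channel Statistics and Simulation of Natural Color Gamuts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining the color statistics of terrestrial scenes.
    Derives the optimal three-band ("parts of daylight") RGB basis from the
    Schroedinger object-color solid under a daylight illuminant; maps RGB
    images through a homomorphic logistic transform to a physical domain and
    an opponent-channel (white-black, red-blue, green-purple) frame;
    summarizes channel covariance by its eigenstructure and the Z statistic;
    fits the power law linking the opponent-channel spreads of image corpora;
    generates random color gamuts from six-parameter signatures, including a
    distortion-robustness simulation; and simulates random reflectance
    spectra with a 1/f^2 articulation spectrum down to the telegraph-wave
    limit that produces Goethe's edge colors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jpeg,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
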