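Package: ecomem
Title: Collective Ecological Memory in Environmental Fluctuation Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models regularly sampled environmental observables (net
    ecosystem exchange, sea surface temperature anomalies, atmospheric
    CO2) as a non-Markovian stochastic process with a power-law memory
    kernel modulated by a sinusoidal envelope. Provides the closed-form
    Bessel-type mean-square displacement (MSD) of the process and its
    short-time power-law asymptote MSD ~ b*T^(2*mu), exact Monte Carlo
    path simulation of the process and of fractional Brownian motion via
    circulant embedding, linear and Fourier spike-removal detrending,
    empirical MSD estimators, deterministic least-squares matching of the
    theoretical MSD to empirical curves with bootstrap confidence
    intervals, Gaussian displacement-probability curves, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
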