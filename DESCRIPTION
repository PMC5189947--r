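Package: eisampler
Title: Hamiltonian Monte Carlo Sampling with Excitatory-Inhibitory Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates probabilistic inference in a model of primary visual
    cortex in which a recurrent excitatory-inhibitory network implements
    Hamiltonian Monte Carlo sampling from the posterior of a Gaussian scale
    mixture (GSM) model of image patches. Provides constructors for the GSM
    generative model and its Gabor-filter basis, the coupled stochastic
    differential equations of the sampler (and a Langevin control without
    recurrent weights), analytic reduced models of the oscillatory dynamics,
    and the neural observables used to characterise them: local field
    potential spectra and spectrograms, sampling-efficiency convergence
    curves, excitation-inhibition balance metrics, and stimulus-onset firing
    rate transients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
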