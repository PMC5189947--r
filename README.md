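# eisampler

Sampling-based probabilistic inference implemented as the dynamics of an
excitatory-inhibitory (EI) neural circuit. The package is for computational
neuroscientists who want to study how cortical dynamics — gamma-band
oscillations, excitation-inhibition balance, and stimulus-onset firing-rate
transients — can emerge from an inference algorithm rather than being bolted
on: here the circuit *is* a Hamiltonian Monte Carlo (HMC) sampler for the
posterior of a Gaussian scale mixture (GSM) model of image patches.

## The model in brief

Images are generated as `x ~ N(z * A u, sigma_x^2 I)` with feature
intensities `u ~ N(0, C)` (the columns of `A` are 15 Gabor filters) and a
nonnegative contrast `z` with a half-normal prior. Given `x` and `z`, the
posterior of `u` is Gaussian with precision
`Sigma(z)^-1 = C^-1 + (z^2/sigma_x^2) A'A`.

The sampler augments each excitatory cell `u_i` with an inhibitory partner
`v_i ~ N(u_i, (M^-1)_ii)` and runs the stochastic dynamics

    du/dt = (W_uu u - W_uv v)/tau + I_input/tau_L + sqrt(2/tau_L) noise
    dv/dt = (W_vu u - W_vv v - I_input)/tau       + sqrt(2/tau_L) noise

with `I_input = (z/sigma_x^2) A'(x - zAu) - C^-1 u` and weight matrices
built from the mass matrix `M = max(0, (A'A)^-1)` so that every synapse has
a fixed sign (Dale's law). The stationary law of `u` is exactly the
posterior; the energy-conserving component produces gamma-band oscillations
whose frequency follows

    f(z) = 1/(2 pi tau) * sqrt(z^2/sigma_x^2 + 1/(1 - sigma_x^2))

(~30/53/102 Hz at contrast 0.5/1/2 with tau = 10 ms, sigma_x^2 = 0.1). The
contrast is inferred jointly by a scalar copy of the same construction, and
deleting the weight matrices leaves a Langevin (noisy gradient ascent)
control with matched noise.

## Worked example

```r
library(eisampler)

net <- default_network()      # 15-filter GSM + EI network, tau = 10 ms
summary(net)
#> EI sampling network summary
#>   cells per population     : 15
#>   tau / tau_L              : 10 ms / 150 ms (ratio 15)
#>   rho^2                    : 13.3 /s
#>   sigma_x^2                : 0.1
#>   eigenvalues of t(A) A    : [0.09, 0.42] (spread 4.67)
#>   predicted LFP peaks (Hz) : 30.2, 53.1, 102.0 at z = 0.5, 1, 2

# simulate stimulus onset (1 s blank, then a contrast-1 stimulus)
traj <- simulate(net, protocol = simulation_protocol(
  t_pre = 1, t_post = 3, z_gen = 1, seed = 1))
traj
#> EI sampler trajectory (hamiltonian mode): 15 cells, 80000 recorded steps
#>   t in [-1, 3] s, onset at 0; fs = 2e+04 Hz
#>   mean inferred contrast after onset: 1.03

# gamma-band LFP peak, trial-averaged over 8 independent stimuli
ps <- lfp_spectrum(net, z_gen = 1, seed = 1)
ps
#> Welch spectrum: 5001 bins up to 1e+04 Hz, peak (power x f) at 54 Hz

# sampling efficiency: time for the running-mean estimate to be worth one
# statistically fair posterior sample
ham <- convergence_curve(net, mode = "hamiltonian", n_reps = 100, seed = 1)
time_to_unit_mse(ham)     # ~0.043 s; the Langevin control needs ~0.28 s

# excitation-inhibition balance
bal <- ei_balance(traj, net)
bal
#> Excitation-inhibition balance
#>   peak cross-correlation 0.973 at lag 1.25 ms (positive: inhibition lags)
#>   per-cell mean E vs I: total-least-squares slope 1.00
```

The peak at 54 Hz is the contrast-1 gamma oscillation (53.1 Hz predicted by
`oscillation_frequency(1)`); the convergence time shows the oscillatory
sampler outpacing its non-oscillatory control by almost an order of
magnitude; the balance summary shows per-cell excitatory and inhibitory
currents matching on average with inhibition trailing by about a
millisecond.

Figure-level experiments (`efficiency`, `oscillations`, `balance`,
`transients`, `rho_sweep`) are orchestrated by `run_experiment()`, which
writes CSV metric tables and a JSON summary; `validate_suite()` runs quick
checks of the structural guarantees. A thin command-line wrapper lives in
`inst/cli/eisampler-cli.R`.

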