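---
title: "Resonance space: damped oscillators, the harmonic operator, and tonal models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resonance space: damped oscillators, the harmonic operator, and tonal models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resotone)
```

## The representation

`resotone` represents a signal — or, in the cognitive reading, a percept —
as a finite sum of *resonances*: complex damped oscillators

$$x(t) = \sum_{k=1}^{K} |d_k|\, e^{i\psi_k}\, e^{-i(\phi_k + i\gamma_k)t},$$

each defined by four real parameters: amplitude $|d_k|$, initial phase
$\psi_k$, centre frequency $\phi_k$, and decay $\gamma_k$. The Fourier
transform of such a signal is a sum of complex Lorentzian peaks,

$$f(\phi) = \frac{i}{\sqrt{2\pi}} \sum_k \frac{d_k}{\phi - \omega_k},
\qquad \omega_k = \phi_k + i\gamma_k,$$

called the resonance spectrum. Unlike a Fourier-basis representation, peak
positions are free parameters placed where the signal actually has
structure, at the price of non-orthogonality: spectra must be compared
through a full pairwise inner product rather than coefficient-wise.

The motivation for taking this representation seriously as a model of
auditory processing is that it falls out of linear dynamical systems. If
neural dynamics near a stationary point are linearized as $x' = Ax$ with
$A = U\Lambda U^*$ (spectral theorem) and observed through a linear
functional $y = b^*x$, then
$y(t) = \sum_k e^{\lambda_k t}\, b^* P_k x(0)$ — exactly a sum of
resonances with $\omega_k = i\lambda_k$ and $d_k = b^*P_k x(0)$. The
`neural_dynamics` functions (`random_system()`, `simulate_observation()`,
`resonances_from_system()`) implement this correspondence and double as
the package's synthetic-data generator; the tests verify the equivalence
to $10^{-8}$ absolute on randomly drawn damped systems (dimension up to 6,
$\mathrm{Re}\,\lambda \in [-2, -0.01]$, $\mathrm{Im}\,\lambda \in
[-50, 50]$, over $t \in [0, 5]$).

## The inner product

Because every resonance is square-integrable (as long as $\gamma \neq 0$;
$\gamma = 0$ is rejected at construction), spectra live in $L^2$ and their
inner product has a closed pairwise form:

$$\langle f|g\rangle = \sum_{j,k}
\frac{i\,|d_j||d_k|\,e^{i(\psi_j-\psi_k)}}
     {(\phi_j-\phi_k) + i(\gamma_j+\gamma_k)}\,\mathrm{sgn}(\gamma_j),$$

summed over pairs with equal decay signs; pairs with opposite decay signs
contribute *exactly* zero (forward-decaying and growing oscillators are
orthogonal). A spectrum may freely mix decay signs; the rule is applied
pairwise. From the inner product come the norm
$\|f\| = \sqrt{\langle f|f\rangle}$, cosine similarity
$s_c = \mathrm{Re}\langle f|g\rangle / (\|f\|\|g\|)$, and cosine distance
$d_c = 1 - s_c$.

```{r}
f <- resonance_spectrum(resonance(amp_mag = 2, phase = 0, freq = 10, decay = -1))
spectrum_norm(f)^2         # = |d|^2 / (2|gamma|) = 2
inner_product(resonance_spectrum(resonance(1, 0, 5,  0.5)),
              resonance_spectrum(resonance(1, 0, 5, -0.5)))  # exactly 0
```

`quadrature_inner_product()` is a deliberately independent numerical
oracle: it integrates $f(\phi)\overline{g(\phi)}$ by adaptive quadrature,
partitioning the axis at the peak frequencies so that narrow Lorentzians
(decays down to $0.01$) sit at subinterval endpoints, with semi-infinite
tail pieces. The closed form and the oracle agree to better than
$10^{-6}$ relative error on batches of random spectra; that agreement is
the core correctness argument for everything built on the inner product.

Two structural invariants worth knowing:

* **Dilation invariance.** Scaling every $\phi$ and $\gamma$ in both
  spectra by $c > 0$ scales inner products by $1/c$ and each norm by
  $1/\sqrt{c}$, leaving cosine similarity unchanged. Musically this is
  transposition invariance, and it is why the tonal models can put the
  tonic at frequency 1 in dimensionless units without loss of generality.
* **Amplitude-scale invariance.** $s_c$ ignores overall loudness.

## Fourier translation and the DFT comparison

On the interval $(-\pi, \pi)$ with orthonormal basis
$\varphi_n(t) = e^{-int}/\sqrt{2\pi}$, a resonance projects onto every
basis function through a complex sinc,
$\langle r_k|\varphi_n\rangle = \sqrt{2\pi}\,\mathrm{sinc}(n-\omega_k)$
(`resonance_fourier_projection()`). Since $\omega_k$ has nonzero
imaginary part, no coefficient vanishes: one damped resonance needs the
whole Fourier basis, while each Fourier coefficient of a $K$-resonance
spectrum is only a $K$-term sum (`spectrum_fourier_coefficient()`). The
conjugation convention is fixed by requiring the printed sinc form to be
the actual integral $\int_{-\pi}^{\pi} e^{-i\omega t}\,e^{int}/\sqrt{2\pi}\,dt$;
the tests confirm it against direct quadrature. The complex sinc uses a
series fallback below $|z| < 10^{-8}$ for the removable singularity.

`dft()` implements the unitary transform
$\hat f_k = N^{-1/2}\sum_n f_n e^{+i2\pi kn/N}$ — note the $+i$ exponent
and $1/\sqrt{N}$ scale, adapted from `stats::fft` (which uses the
opposite sign, unnormalized). Its fixed grid (`dft_bin_frequencies()`)
is the contrast case: a 60 Hz sine sampled at 44.1 kHz over 1024 samples
has no bin at 60 Hz and leaks power everywhere, whereas the resonance
representation simply places a peak at 60 Hz.

## The harmonic operator

`apply_harmonic()` maps each resonance to $N$ overtones: the $(k,n)$
member has frequency $n\phi_k$, phase $n\psi_k$, the *seed's* decay
$\gamma_k$ (not scaled with $n$), and amplitude $A(\cdot, n)\,|d_k|$
under an attenuation function $A$. $H$ is linear over amplitude scaling
and concatenation, exactly. Attenuation families
(`attenuation_spec()`):

| family | weight | notes |
|---|---|---|
| `constant` | $c$ | default $c = 1$; the form the fitted tonal model selects |
| `power_law` | $1/(n^\alpha+\beta)$ | $\alpha=1,\beta=0$ is the classic $1/n$ rolloff |
| `one_over_f` | $1/\phi$ at the overtone frequency | the only frequency-dependent family; where $A$ depends on frequency it is evaluated at the overtone's centre $n\phi_k$ |
| `table` | explicit per-$n$ weights | |

The specialized sums `inner_product_with_harmonic()` ($\langle f|Hg\rangle$,
attenuation applied to $g$'s overtones) and
`harmonic_harmonic_inner_product()` ($\langle Hf|Hg\rangle$) are
implemented independently of the expand-then-inner-product route and must
agree with it to $10^{-12}$ relative; the tests enforce this on random
inputs. $N$ is always finite (default cap 256); unbounded-operator
behaviour as $N \to \infty$ is out of scope.

## Tonal models

A key is modelled by its tonic triad: three resonances at the fundamental
frequencies of the triad tones in 12-tone equal temperament (semitone
offsets $\{0,4,7\}$ major, $\{0,3,7\}$ minor), amplitudes
$(1, |d_2|, |d_3|)$, phases 0, one shared positive decay $\gamma_0$. A
just-intonation option (4:5:6 / 10:12:15) exists for exploration but all
fits use equal temperament. Free parameters and their meaning:

* $\gamma_0 > 0$ — spectral peak width (dimensionless, tonic at
  frequency 1). Wider peaks mean more tolerance for mistuning; the sweep
  peak width at 90% height grows monotonically with $\gamma_0$.
* $|d_2|, |d_3| \in [0,1]$ — salience of the third and fifth relative to
  the tonic.

**Key affinity** of a pitch for a key is $s_c(Hf, Hg)$ between the
harmonic spectra of the key triad and of a single-resonance probe pitch;
`affinity_profile()` evaluates it at the 12 semitones and
`affinity_sweep()` on a geometric frequency grid (default 1200 points =
1-cent steps, so semitones are equally spaced on the axis). The probe
pitch reuses the key's $\gamma_0$: its decay is not separately
identified by the data, and sharing it keeps the model at three free
parameters. **Inter-key distance** is $d_c(Hf, Hg)$ between two triads'
harmonic spectra; `distance_profile_set()` returns the four panels
(major/minor reference against the 12 major and 12 minor keys), and the
24-key enumeration everywhere is majors C..B then minors C..B.

With the flat attenuation and $N = 12$ overtones, the best-fit affinity
parameterization lies near $\gamma_0 \approx 0.03$, $|d_2| = 0.672$,
$|d_3| = 0.420$; an octave-related probe is *not* equivalent to the
tonic (a finite overtone stack shares only half its overtones with its
octave), but both are high-affinity peaks and the tritone is the
low-affinity floor.

## Fitting

`fit_profile_model()` maximizes the Pearson correlation between the
model's concatenated profile vector (24 values for affinity: major then
minor profile; 48 for distance: four panels) and the targets. Pearson
correlation is affine-invariant, so no scale or location parameters are
estimated, and rank-based alternatives are not used (product-moment is
the convention of the comparator literature). The optimizer is
multi-start Nelder–Mead on transformed parameters ($\gamma_0$
log-logistic in $[10^{-3}, 0.5]$, amplitudes logistic in $[0,1]$,
power-law $\alpha \in [0.01, 4]$, $\beta \in [-0.9, 20]$ with
$n^\alpha + \beta > 0$ guarded), started from a fixed $3\times3\times3$
grid, so fits are deterministic; the seed only feeds optional extra
random starts. The objective is a smooth 3–5 parameter surface and the
correlation attains exactly 1 on noiseless self-generated targets, which
is what makes parameter recovery a sharp test: the suite demands
recovery within 5% relative (noiseless) and 15% (Gaussian noise,
$\sigma = 0.01$ on similarity values).

`sweep_overtone_count()` refits the flat-attenuation model per overtone
count $N$ and reports the per-$N$ best correlations and their mean; on
targets generated by the model itself with a known $N$, the argmax
recovers that $N$. `score_distance_fixture()` evaluates a *fixed*
distance parameterization ($\gamma_0 = 0.0402$, $|d_2| = 0.925$,
$|d_3| = 1$, $N = 12$ is the reference setting) against an independent
target table without refitting.

The internal objective uses a reduced real kernel: with all phases zero
and a shared $\gamma_0$, each pairwise term's real part is
$a_j a_k \cdot 2\gamma_0/(\Delta\phi^2 + 4\gamma_0^2)$. The tests pin
this fast path against the generic complex route.

## Data, fixtures, and what the tests do and do not show

The package ships one external data table: a transcription of the
Krumhansl–Kessler probe-tone rating profiles (major and minor, 12 values
each) in `inst/extdata/`, loaded by `kk_profiles()`. Fitting the
affinity model to it reproduces correlations near 0.95 on both profiles
(asserted at ±0.01 in the acceptance tests), and freeing the power-law
attenuation on these targets collapses it to an effectively constant
function (max/min weight ratio below 1.1 over $n \le 12$) — the
empirical justification for the flat default. Scalar inter-key distance
tables derived from the toroidal multidimensional-scaling solution, and
perceived triadic-distance ratings, are not redistributable here; the
loaders accept user-supplied transcriptions in the same CSV schema, and
the fixture-dependent checks run when such files are present.

Everywhere else, targets are generated by
`generate_synthetic_targets()`: the model evaluated at known parameters
plus seeded Gaussian noise. Synthetic targets exercise identifiability,
determinism, and optimizer correctness, but they inherit the model's own
functional form — they cannot detect misspecification against real
probe-tone data, and noiseless recovery says nothing about how listener
rating noise (which is not i.i.d. Gaussian across semitones) propagates.

Problem sizes were chosen to keep every check sharp but cheap: oracle
batches of 100 random spectra with $K \le 5$, $|\phi| \le 50$,
$0.01 \le |\gamma| \le 2$; dynamical systems up to dimension 6; sweeps
over a handful of overtone counts around the generating value. Numerical
tie-breaks and guards worth noting: cosine similarity clips roundoff
spill just outside $[-1,1]$; the $\gamma \neq 0$ construction invariant
keeps every closed-form denominator away from zero; quadrature failures
raise rather than return partial sums; JSON and CSV writers emit 17
significant digits so round trips are bit-exact.

## Known limitations

* Estimating resonances *from* sampled audio is out of scope by design;
  spectra enter as parameter lists.
* The distance model's reference tables must be supplied by the user;
  only the probe-tone profiles ship with the package.
* Non-normal (non-unitarily-diagonalizable) system matrices are rejected
  rather than handled; the eigenmode correspondence assumes the spectral
  theorem applies.
* Stochastic inputs and observation noise in the dynamical model are
  omitted; the equivalence demonstrated is for the deterministic,
  linearized system.
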