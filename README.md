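# iicp — improved iterative closest point registration for surface scans

`iicp` rigidly registers 3-D point clouds for surface-matching problems of
the kind that arise in image-guided surgery: aligning a sparse, noisy,
partially overlapping depth-sensor scan (the *floating* cloud) to a dense
CT-derived surface (the *reference*), with accuracy judged by the target
registration error (TRE) at labelled fiducial markers rather than by the
fitting residual alone.

## The method

Classic point-to-point ICP alternates nearest-neighbour matching with the
least-squares (Kabsch) rigid fit and converges only to the nearest local
optimum. The improved variant implemented here (I-ICP) adds two mechanisms:

**Median weighting.** With match distances \(d_i\) and their median \(m\)
(taken at the sorted 1-based index \(N/2\) for even \(N\), \((N+1)/2\) for
odd), each correspondence is weighted

\[\delta_i = \begin{cases}1 & d_i \le m\\ m/d_i & d_i > m\end{cases}\]

and the registration objective is the weighted evaluation value
\(\mathrm{RMS} = \tfrac{1}{N_F}\sum_i \delta_i d_i\). Matches worse than
typical — wrong pairings from non-overlapping regions, many-to-one
pile-ups, outliers — are damped in both the objective and the transform
estimate.

**Stochastic perturbation with golden-section refinement.** When an outer
round fails to improve, the six transform parameters (extrinsic XYZ Euler
angles + translation) are jumped by independent draws from the parabolic
density \(p(y) = 3y^2/(2(\alpha\gamma_k)^3)\) on
\((-\alpha\gamma_k,\alpha\gamma_k)\) — mass concentrated near the ends, so
basin-clearing jumps are favoured — where \(\gamma\) is the parameter step
the search last took and \(\alpha\) expands geometrically (×1.5, capped at
20) while rounds keep failing. A golden-section search
(\(\varphi \approx 0.618\)) along the best-to-proposal segment refines the
restart point, and the best transform ever seen is always retained. TRE at
marker \(i\) is \(\|p_i^{valid} - p_i^{f}\|\).

## Worked example

```r
library(iicp)

# A synthetic scan-to-surface case with known ground truth: 2,000-point
# head-shaped reference, 500-point scan with 70% overlap, 1 mm noise, 2%
# outliers, displaced by a 30-degree rotation about the (1,1,1) diagonal
# plus a 100 mm translation.
case <- makeRegistrationCase("head_ellipsoid", seed = 1)

res <- registerIICP(case@floating, case@reference, registrationConfig(seed = 1))
res
#> RegistrationResult (median weighting, seed 1)
#>   best objective: 1.24729 mm after 8 accepted bests
#>   inner iterations: 5716, perturbation restarts: 99, stopped: max_rounds
#> RigidTransform
#>   rotation (deg, extrinsic XYZ): 20.114 14.078 20.058
#>   translation (mm): 57.759 57.645 57.730

# Accuracy at the five labelled markers, against the known truth:
registered <- applyTransform(resultTransform(res), case@floating)
targetRegistrationError(markers(case@reference), markers(registered))
#> TREReport over 5 markers
#>   label            x           y            z       tre
#> 1    M1 -0.008240062 -0.11157816 -0.004821063 0.1119858
#> 2    M2  0.045250346  0.04714677 -0.107783332 0.1260463
#> 3    M3 -0.017816066  0.01359308 -0.112477529 0.1146882
#> 4    M4 -0.057031185 -0.01496364 -0.109080901 0.1239964
#> 5    M5  0.090725983 -0.04770978 -0.006661647 0.1027220
#>   per-axis mean |error| (mm): x 0.044  y 0.047  z 0.068
#>   mean TRE: 0.116 mm
```

The final objective (~1.25 mm) sits at the noise floor of the 1 mm scan
noise; the mean marker TRE of 0.12 mm shows the recovered transform is
within a tenth of a degree/millimetre of the ground truth. The classic
baseline `registerICP()` on the same case stalls in a local optimum —
compare with `benchmarkRun(case, c("iicp", "icp"))`.

A command-line wrapper is included:

```sh
Rscript inst/cli/iicp.R simulate --kind head_ellipsoid --seed 1 --out case/
Rscript inst/cli/iicp.R register --reference case/reference.ply \
    --floating case/floating.ply --method iicp --seed 1 --out run/
Rscript inst/cli/iicp.R evaluate --case case/ --transform run/transform.json
```

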