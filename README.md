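# nmrmap

Solution-NMR interaction mapping for protein–peptide complexes.

When a peptide ligand binds a multidomain protein in fast exchange on the
NMR time scale, the binding site and binding mode can be mapped without a
crystal: backbone amide peaks shift with the bound population, a nitroxide
spin label on the ligand bleaches the signals of nearby residues, and ¹⁵N
relaxation reports how each domain tumbles before and after binding.
`nmrmap` implements that whole analysis as composable R functions, for NMR
spectroscopists and structural biologists working from assigned
¹H–¹⁵N peak lists (Sparky text or CSV):

- **CSP mapping** — the combined perturbation per residue,
  CSP = √((Δδ¹⁵N/10)² + (Δδ¹H)²), with significance at mean + 1 SD of the
  whole-construct distribution.
- **Fast-exchange K_D fitting** — observed shifts follow
  Δδ_obs = f_bound·Δδ_max with the exact quadratic isotherm
  f_bound = ((P+L+K_D) − √((P+L+K_D)² − 4PL)) / 2P; one shared K_D is
  profiled over all responsive residues.
- **PRE analysis** — I_para/I_dia ratios normalized so distant residues
  average exactly 1 (correction factor α), calibrated linearly to distance
  (PRE 0 → 12 Å, PRE 1 → 30 Å), and converted into semiquantitative
  docking restraints: vanished peak → [1.8, 12] Å; 0 < PRE < 0.8 →
  [12, d_calc + 3] Å; PRE ≥ 0.8 → unrestrained. Restraints export to
  CNS/HADDOCK `.tbl` or CSV.
- **¹⁵N relaxation** — monoexponential R1/R2 fits with signal-to-noise
  based Monte-Carlo errors; per-domain apparent correlation time
  τc = √(6·R2/R1 − 7) / (4π·ν_N) from the 1-SD-trimmed mean ratio;
  exchange flagging above mean + 1 SD; Welch tests between conditions.
- **Competition classification** — three-condition experiments
  (free / +client / +client+competitor): a residue whose significant
  client CSP grows further on adding the competitor is called
  `competitive`; disappearing peaks are `broadened`.
- **Structure comparison** — Kabsch (SVD) superposition and Cα RMSD
  between PDB models, with a grid scan over model/range choices.
- **Synthetic data** — seeded generators for every observable with the
  ground truth returned alongside, so each stage is testable end to end.

## Worked example

Simulate a titration of a 2 mM-K_D peptide into a 1 mM ⁠¹⁵N-labelled
81-residue domain (binding site residues 30–48, 0.002 ppm position
noise), then map the site and recover the affinity:

```r
library(nmrmap)

g <- gen_titration(seed = 7, n_res = 81, kd = 2e-3, p_conc = 1e-3,
                   noise_ppm = 0.002)
free  <- g$series$peaklists[[1]]   # ligand-free reference
bound <- g$series$peaklists[[6]]   # 4 mM ligand

prof <- csp_profile(free, bound,
                    domains = domain_map(c("J-domain", "tail"),
                                         c(1, 73), c(72, 81)))
summary(prof)
#> CSP profile: 81 residues, 19 significant (threshold 0.0400 ppm)
#>   J-domain: 30 31 32 33 34 35 36 37 38 39 40 41 42 43 44 45 46 47 48

fit <- fit_kd_fast_exchange(g$series)
fit
#> <binding_fit>  K_D = 0.00198 M (sigma 0.00012), 81 residues, RSS 0.00115
```

The significant set is exactly the designed site, and the shared-K_D fit
returns 1.98 mM against a truth of 2 mM. Closed-form correlation times
from measured R2/R1 domain averages at a 900 MHz ¹H field:

```r
round(tauc_from_ratio(c(22, 70), 900), 2)
#> [1]  9.75 17.73
```

i.e. ≈9.8 ns for a flexible arm tumbling semi-independently and ≈18 ns
for a rigid dimeric core. `run_pipeline(pipeline_config(...))` wires the
stages together from files on disk and writes per-residue CSVs, a
restraint table and an auditable run log.

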