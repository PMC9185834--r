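# crowdfate file formats

## Run configuration

Flat `key = value` text, `#` comments. Dotted keys group by module; CLI
positional `key=value` arguments override the file. Common keys:

| key | default | meaning |
|---|---|---|
| `rates.M` | 1 | movement attempt probability per step |
| `rates.P` | 0.006 | growth attempt probability per step |
| `domain.L` | 100 | domain width (lattice columns / PDE domain) |
| `domain.A` | 0.4 | Allee threshold |
| `domain.w` | — | initial strip width (required where used) |
| `model.kind` | catalogue | `catalogue`, `powerlaw` or `expression` |
| `model.name` | — | catalogue name (`linear`, `increasing`, `decreasing`, `powerlaw-m1..3`) |
| `model.m` | — | power-law exponent (kind `powerlaw`) |
| `model.expression` | — | arithmetic expression in `C` (kind `expression`) |
| `seed` | 1 | base random seed |
| `pde.h`, `pde.tend`, `pde.record` | 0.5, 1e4, tend | solver grid, horizon, comma-separated output times |
| `abm.V`, `abm.tend`, `abm.record` | 10, 600, tend | ensemble size, horizon, output times |
| `flux.t0`, `flux.t1` | 0, tend | flux tally window |
| `phase.models`, `phase.w`, `phase.ratio`, `phase.T`, `phase.tol_w` | linear, 0:40:41, 0.001:0.04:40, 1e4, 0.25 | phase-diagram mesh (`lo:hi:n`) |
| `tabulate.n` | 101 | tabulation grid size |

## CSV outputs

- `crowding.csv` — `C, G, dGdC, D, H` (tabulate-crowding).
- `profiles.csv` — `t, x, C` long format (solve-pde).
- `total_density.csv` — `t, total_density[, stderr]` (solve-pde, simulate-abm).
- `column_density.csv` — `t, x, mean_density, stderr` (simulate-abm).
- `flux.csv` — `x, Jx, se`; `x` are the tally lines `(k + 3/4)·Δ` (measure-flux).
- `critical_width.csv` — `model, P_over_M, w_star, tol_w` (critical-width).
- `outcomes.csv` — `w, P_over_M, model, outcome` with outcome in
  `survive/extinct/undecided`; `boundary.csv` — `model, P_over_M, w_star`
  (phase-diagram).

## State snapshots

- Site-list CSV: `i, j, x, y, occupied` (one row per lattice site).
- Run-length text: header `hexstate I J delta`, then `value count` pairs over
  site order (column-major by row index `j`).

## manifest.json

Written once per run directory: `command`, package `version`, `seed`,
`started`/`finished` wall times, the effective `config` (echoed as parsed;
re-parses to an identical configuration) and `outputs` (basename to MD5
checksum). Re-running with the manifest's config and seed reproduces
stochastic outputs bit-identically.

## Exit codes (inst/cli/crowdfate.R)

`0` success, `2` configuration error, `3` numerical failure, `4` undecided
fate at the decision horizon.
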