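# File formats used by the `bdtree` CLI

## Newick trees

Standard single-line Newick, semicolon-terminated, written by
`write_newick()` through `ape::write.tree()`.

- Branch lengths are durations in model time units and are mandatory.
- The tree is rooted and strictly binary; polytomies are rejected on
  read with the offending internal vertex named.
- The stem (root lineage from time 0 to the first split) is stored as
  the root edge, e.g. `(1:1,2:1):0;` for a cherry whose split happens
  at time 0.
- Tip labels are species numbers in order of creation: the original
  lineage is `1`, at each split the continuing lineage keeps its label
  and the new lineage takes the next integer.
- On read, absolute times are reconstructed with the root lineage
  starting at time 0.

## CSV tables

All CSV outputs carry a header row; floats are serialized with 12
significant digits.

- `pmf`: columns `m, probability`; the tail mass beyond the table is
  logged to stderr.
- `immsim`: one row per replicate, columns `Z, F, C1..Cmax`.
- `esf`: columns `partition` (multiplicities `c_1 .. c_n`,
  space-separated) and `probability`.
- `fisher`: long format `quantity, value, se` (`t1`, `t2`,
  `EV2_times`, `EV2_sizes`, and `EV2_mc` when `--simulate` is given).
- `cellsim`: summary row `S, b1..b9, truncal`; with `--sfs-out`, the
  spectrum as `j, f`.
- `abc build-table`: reference table `p, theta, S, b1..b9, truncal`.
- `abc infer`: posterior `row, p, theta, weight`.

## JSON configuration (`abc build-table --config`)

```json
{
  "N": 1000, "n": 100,
  "priors": { "p": [0.5, 0.8], "theta": [10, 20] }
}
```

Omitted fields fall back to the package defaults.

## Seeds

Every stochastic subcommand requires `--seed <int>`; identical command
lines produce byte-identical outputs. Reference-table rows derive
per-row substreams from the table seed, so row k is reproducible in
isolation.
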