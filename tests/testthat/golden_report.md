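# Absorbed doses per administered activity (mGy/MBq)

| Organ | Centre | n | Median (range) |
|---|---|---|---|
| whole-body | 1 | 5 | 0.05 (0.04-0.06) |
| whole-body | 2 | 5 | 0.05 (0.04-0.06) |
| whole-body | 3 | 4 | 0.05 (0.04-0.14) |
| whole-body | 4 | 6 | 0.05 (0.03-0.17) |

## Whole-body group comparisons

- activity group: 1.1 GBq median 0.05 (n=4) vs 3.7 GBq median 0.05 (n=16); Mann-Whitney U = 33.0, p = 0.9635 (exact)
- stimulation: rhTSH median 0.05 (n=16) vs THW median 0.04 (n=4); Mann-Whitney U = 48.0, p = 0.1482 (exact)
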