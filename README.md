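# viromegrad

Tools for profiling soil viromes and phage–bacterium interactions along an
environmental stress gradient, such as the decreasing geochemical gradient
around a heavy-metal (chromium) contamination source. The package is aimed
at microbial ecologists who have assembled contigs with per-gene annotation
tables in hand and want the downstream decision rules — viral contig
identification, host linkage, lysogeny and auxiliary-metabolic-gene
analysis — as explicit, tested, reusable functions rather than one-off
scripts.

## What it computes

- **Viral contig identification.** Strict >5 kb length gate, then a contig
  is viral if its VirSorter category is in {1, 2, 4, 5}, or if its gene
  annotations satisfy any of three criteria on the counts of genes with
  viral-protein-family (VPF), Pfam and KO hits:
  (a) n_vpf ≥ 5 ∧ n_ko/n < 0.20 ∧ n_pfam/n ≤ 0.40 ∧ n_vpf/n > 0.10;
  (b) n_vpf ≥ n_pfam; (c) n_vpf ≥ 0.60·n. Boundary comparisons are done on
  exact integer rationals.
- **CRISPR host linkage.** Full-length exact spacer–protospacer matches on
  either strand (the E ≤ 1e-10 / 100% identity criterion realized as a
  minimum exact-match length, default 20 nt). Contigs linked to ≥ 2 distinct
  host genera are polyvalent (broad host range).
- **Lysogeny.** Integrase (Pfam) carriage flags lysogenic phages; per-sample
  indicators are the TPM-weighted lysogen share of the free virome, the
  integrase percentage of the bacterial metagenome, and the mitomycin-C
  induction assay X = (V_i − V_ck)/B in VLP per cell.
- **MRG screening.** Percent of viral-gene TPM in metal-resistance gene
  (membrane transporter / reductase) KO lists, and the fraction of MRG genes
  carried by lysogen-flagged contigs.
- **Gene-sharing networks.** Hypergeometric similarity score
  −log10(P(X ≥ c)·T) over shared protein clusters; edges at score ≥ 1;
  viral clusters as connected components.
- **Community statistics.** TPM normalization, bias-corrected Chao1, ACE,
  strict dominance filters, Kruskal–Wallis gradient tests.
- **Synthetic community generator.** `generate_community()` produces
  contigs, annotations, spacer libraries, counts, metagenome tables and
  induction triplets along a configurable stress gradient, with a
  ground-truth manifest the pipeline recovers *exactly* in the noiseless
  case — the basis of the validation suite.

## Worked example

```r
library(viromegrad)
bundle  <- generate_community(gradient_config(seed = 7))
profile <- run_virome_pipeline(bundle)
profile$samples[, c("sample_id", "stress", "lysogen_fraction",
                    "polyvalent_fraction", "induced_per_cell")]
#>   sample_id stress lysogen_fraction polyvalent_fraction induced_per_cell
#> 1        L1   0.05           0.0383               0.105            0.227
#> 2        L2   0.10           0.0657               0.168            0.711
#> 3        L3   0.40           0.1363               0.456            5.613
#> 4        Z1   0.10           0.0530               0.248            0.752
#> 5        Z2   0.45           0.2578               0.337            7.045
#> 6        Z3   0.75           0.2239               0.432           15.042
#> 7        Z4   1.00           0.4231               0.535           21.869
```

The seven default samples emulate two contaminated sites (L1–L3 lightly,
Z1–Z4 heavily polluted). Reading the columns: at the highest stress the
lysogenic phages make up ~42% of virome abundance versus ~4% at the lowest;
polyvalent phages rise from ~10% to ~54%; and the induction assay climbs
from 0.2 to ~22 induced phages per cell. Attribution of metal-resistance
genes shows the lysogen reservoir effect:

```r
profile$mrg_attribution
#>   on_lysogen_transporter on_lysogen_reductase n_transporter_genes n_reductase_genes
#> 1              0.6666667                 0.68                  18                25
```

i.e. about two-thirds of the MRG cargo sits on lysogenic phages. All of
these trends are generated, recovered and tested against the generator's
ground-truth manifest.

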