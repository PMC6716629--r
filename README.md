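# bimotif

Ab initio discovery of **bipartite DNA motifs** — transcription factor
binding sites made of two conserved blocks separated by a weakly
constrained spacer of variable length, written `l_L<[d_min,d_max]>l_R`
(e.g. the bacterial sigma-factor promoter elements `TTGACA<spacer>TATAAT`).
The package is for regulatory-genomics analysts who have a set of
pre-oriented binding-region sequences and want the shared two-block motif,
its probability matrices, and quantitative evaluation against known sites.

## The method

Given `N` sequences and user-chosen block widths and gap range, the search
assigns each sequence a placement (left-block start and gap length) so as
to minimize the information content of the concatenated motif blocks
against the background,

    IC = sum_i sum_x  -p_i(x) * log2( p_i(x) / b(x) )

where the columns `i` run over motif positions (mononucleotide PWM,
alphabet size k = 4) or over adjacent within-block base pairs
(dinucleotide DWM, k = 16, which captures nearest-neighbour
interdependencies that a PWM cannot express), and

    p_i(x) = (f_i(x) + beta/k) / (N_eff + beta)
    b(x)   = (g(x)  + beta/k) / (n + beta)

with total pseudo-count `beta = 1`, `f_i` the site tallies, and `g`/`n`
the composition of everything *not* covered by motif blocks (the
background is placement-dependent and is updated with every move). Lower
IC means a sharper motif; a motif identical to the background scores 0.

The optimizer is a Gibbs-sampling-style scheme: placements are
initialized at random, then per-sequence greedy updates re-place one
sequence at a time at the exact argmin of the total IC, sweeping until the
entropy change drops below `epsilon = 1e-8`; many random restarts
(default 100) are run and the best final entropy wins. Occurrence modes:
OOPS (one site per sequence), ZOOPS (zero or one; an occurrence is kept
when its log-odds beats the position-encoding cost `log2(#placements)`
plus a user threshold), and ANR (any number of repeats, placed by a final
non-overlapping scan).

Evaluation utilities implement the nucleotide-level correlation
coefficient (nCC) between predicted and known sites, its pooled
("combined") form across datasets, sequence-level TPR/FPR for
noise-spiking benchmarks, and the pairwise positional mutual-information
matrix used to visualize base interdependencies. A synthetic-data module
generates benchmark datasets with planted bipartite motifs, tunable
conservation, gap distributions, Markov backgrounds, motif-free noise
sequences, and dependency-engineered blocks whose per-position marginals
are uniform but whose adjacent pairs carry tunable mutual information.

## Worked example

```r
library(bimotif)

spec <- bipartite_spec(6, 6, 8, 12)          # 6<[8,12]>6, PWM, OOPS
cfg  <- synth_config(40, 100, spec,
                     left_model  = consensus_pwm("TTGACA", 0.9),
                     right_model = consensus_pwm("TATAAT", 0.9),
                     seed = 7)
d   <- synth_generate(cfg)
res <- bimotif_search(d$sequences, spec, search_config(restarts = 40, seed = 2))
print(res)
#> bipartite motif spec 6<[8,12]>6  (mononucleotide matrix, OOPS mode)
#> final entropy: -15.893391 bits (best of 40 restarts)
#> sites placed: 40 of 40 sequences
#> consensus: TTGACATATAAT

lens <- setNames(nchar(d$sequences$seq), d$sequences$id)
pred <- placements_to_sites(res$placements, spec, d$sequences$id)
ncc(confusion_counts(d$truth, pred, lens))
#> [1] 0.9619345
```

The printed entropy is the minimized IC in bits (more negative = more
conserved relative to background); the consensus concatenates the two
blocks; the final number is the recovery nCC against the planted truth
(1 = perfect per-base agreement). `export_matrix()` writes the
position probability matrix for logo tools, `write_placements()` the
per-sequence site report.

A command-line wrapper with `find`, `evaluate`, `simulate` and `mi`
subcommands ships in `inst/cli/bimotif`:

```sh
Rscript inst/cli/bimotif find --input sites.fasta --left 6 --right 6 \
    --gap-min 11 --gap-max 23 --matrix dwm --restarts 100 --seed 1 \
    --out-prefix run1
```

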