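---
title: "Finding selenoprotein genes by in-frame TGA exon assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding selenoprotein genes by in-frame TGA exon assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Selenoproteins carry selenocysteine (Sec, `U`), the 21st amino acid, encoded
by the TGA codon that every standard gene annotation pipeline reads as a
stop. An annotator that treats TGA as a terminator truncates a selenoprotein
model at the Sec codon or discards the gene outright, which is why
selenoprotein genes are systematically mis-annotated in published protein
sets. Recoding is directed in *cis* by a SECIS element -- a stem-loop in the
3' untranslated region -- and the gene itself usually has a cysteine-form
homolog in which the Sec column is occupied by Cys.

`selenoscan` turns these observations into a pipeline:

1. scan the genome for gene signals (ATG, TAA/TAG, GT donors, AG acceptors,
   and every TGA codon);
2. enumerate typed exon candidates from those signals, keeping exons whose
   reading frame contains TGA rather than rejecting them;
3. for every exon carrying an in-frame TGA, assemble the
   maximal-coding-potential open reading frame that contains it, by dynamic
   programming over splice-compatible exon chains;
4. translate the model with TGA as `U` and demand Sec/Cys ("U/C") pairing
   against a protein database;
5. demand a SECIS element downstream of the stop; ESTs spanning the
   TGA corroborate read-through but are reported, not required.

Calls passing both U/C pairing and the SECIS check are confirmed, labelled
with a family, summarised into per-organism count tables, and screened for
tandem gene clusters.

## Scores and models

**Coding potential.** Every exon candidate is scored as the sum of its
signal scores plus a coding log-likelihood ratio, all in bits. Signals are
scored by position weight matrices (log-odds against the genomic base
composition) over fixed windows: start $-6..+5$ around the ATG, donor
$-3..+6$ around the GT, acceptor $-14..+2$ around the AG. The likelihood
term comes from an order-$k$ Markov model, three-periodic on the coding
side (one transition table per codon phase) and homogeneous on the
noncoding side:

$$\mathrm{LLR}(x) = \sum_i \log_2 P_c(x_i \mid x_{i-k..i-1}, \phi_i)
                    - \log_2 P_{nc}(x_i \mid x_{i-k..i-1}).$$

The default order is $k = 5$ with an additive pseudocount of 1, the
convention of classical HMM/Markov gene finders. Positions without a full
context, and positions involving `N`, contribute zero; windows containing
`N` cannot host signals. Sec-TGA codons in training CDS are ordinary coding
triplets.

**Exon typing and frames.** Candidates are `initial` (ATG to donor),
`internal` (acceptor to donor), `terminal` (acceptor to stop) or `single`
(ATG to stop). `frame5` is the number of bases of the spanning codon already
consumed upstream and `frame3 = (frame5 + length) mod 3`; two exons are
splice-compatible when `frame3` of the first equals `frame5` of the second,
the gap is at least the 40 nt intron minimum, and the codon split across the
junction is not TAA/TAG. A junction codon that reads TGA is a legitimate
Sec codon and is recorded. No emitted exon contains a complete in-frame
TAA/TAG; in-frame TGAs are listed, never rejected -- this is the single
change that lets the machinery see selenoprotein genes at all. A model's
terminal stop must be TAA/TAG: in confirmed selenoprotein genes TGA
essentially never acts as a stop, so the assembler does not allow it to.

**Chain assembly.** The best gene through a focal TGA-carrying exon is the
chain maximising total coding potential minus an intron cost, computed as a
forward pass (best prefix from an initial exon) plus a backward pass (best
suffix to a terminal exon). The intron cost is an opening penalty of 5 bits
plus 0.02 bits/nt of intron length. The linear term matters twice over:
without it, any chain could be extended through a neighbouring gene's exons
at zero marginal cost (extra exons only ever add score), and with it the
recurrence keeps a prefix-maximum structure -- the quantity
$\mathrm{prefix}(a) + c \cdot \mathrm{end}(a)$ is what each
(phase, junction-fragment) bucket must maximise, so the sweep is linear in
the number of candidates. Ties break toward fewer exons, then the leftmost
gene start. Models from different focal TGAs sharing at least half of their
coding bases are collapsed to the best-scoring one. Exon enumeration keeps
at most 50,000 candidates per Mb (by score), and exon lengths are bounded
to 30--6,000 nt; these bounds are tractability choices, not biology.

**U/C pairing.** Up to 20 residues around each Sec are aligned
(Smith-Waterman, BLOSUM62, gap open 11 / extend 1, with `U` scored as `C`)
against the protein database; a subject placing Cys opposite the query's
`U` column at >= 30% aligned identity and above a raw-score threshold counts
as pairing evidence. The score threshold stands in for a BLAST E-value
cutoff: it is calibrated per run as the 99th percentile of scores against
residue-shuffled database entries, which needs no database-size statistics.
Sec-form homologs (subject `U`) count as Cys under the same convention.

**SECIS detection.** The detector enumerates stem-loops anchored on every
TGA in a 3,000 nt window downstream of the stop: helix I (6--16 bp),
internal loop (1--20 nt per side), helix II (8--18 bp) whose first four
pairs form the non-Watson-Crick quartet opening with UGA and preceded by an
unpaired A or G, and an apical loop (8--22 nt) containing AA. The motif
class is `AUGA_AA` or `GUGA_AA` according to that preceding base. The score
is additive -- $2 \cdot \mathrm{WC} + 1 \cdot \mathrm{GU} - 0.5 \cdot
(\text{loop nt beyond minima}) + 3$ for the complete core motif -- and is
deliberately *not* a covariance-model score; it is not comparable to
published Cove scores. The default acceptance threshold of 24 was
calibrated once against uniform-random sequence: the best structure in a
random 300 nt window essentially never exceeds ~21, while elements built at
the generator's default geometry score 28 or more, so the threshold sits in
a wide margin between the two populations (fewer than 1% of random 300 nt
windows produce a hit, and in-range planted elements are always recovered).

## The synthetic benchmark

Real selenoproteome surveys need hundreds of Mbp of assembled genome and a
large protein database; the package instead ships a generator that plants
ground-truth genes in synthetic chromosomes so that every stage is testable
end to end. The default benchmark is 2 Mb of i.i.d. background at GC 0.40
carrying 20 selenoprotein genes (1--9 exons of >= 35 nt, 120--400 codons,
1--3 Sec codons, one SECIS each -- 15% get two, mirroring the rare
dual-SECIS architecture), 5 pseudogene decoys (complete gene structure and
homolog support but no SECIS), 5 Cys-paralog decoys (TGC in place of TGA),
a homolog database mutated to 60% identity with `U -> C`, and 2,000 ESTs of
150--600 nt at 1% substitution error, all under seed 42. Coding sequence is
drawn from a codon-usage table itself drawn per genome, so the scoring
model must be *estimated* rather than matched; splice sites are planted
with donor `GTAAGT` and a pyrimidine-rich acceptor tail, and starts with a
Kozak-like context, giving the PWMs genuine signal to learn. Scoring models
are trained on the planted annotation itself (`fit_models_from_truth()`),
as one would train on a curated gene set for a real genome; signal
thresholds are set from the training-site score distribution (5th
percentile minus 1 bit, floored half a bit under the weakest training
site, so annotated sites are never lost).

What the generator does *not* emulate -- repeats, isochore GC structure,
sequencing error in the assembly, alternative splicing, degenerate or
type-2 SECIS topologies -- bounds what a passing benchmark shows: the
machinery is correct and well calibrated on clean planted structure, not
that real-genome sensitivity will be 100%.

A dedicated fixture reproduces the most demanding published architecture,
a selenoprotein-P-like gene with 8 coding exons, Sec codons on coding exons
1, 3 and 5 plus two near the C-terminus, and two SECIS elements. The locus
is synthetic: it mirrors the architecture, not any published sequence. The
spliced mapper recovers its 8 exons exactly, the translation carries 5 `U`
residues, and the SECIS scan returns both elements.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and BED conversions happen only at the file boundary and round-trip
  exactly.
* Minus-strand genes are found by scanning the reverse complement and
  reflecting coordinates, so there is one scanner code path; `sec_positions`
  are genomic starts of the TGA codons.
* Confirmation requires **both** U/C pairing and at least one SECIS, in the
  order the stages run (homology first, SECIS as the final confirmation);
  EST support is annotation. A candidate failing earlier stages is written
  to the audit file with the first failed criterion; SECIS is not evaluated
  for candidates that already failed pairing. One gene per SECIS: when two
  confirmed models on the same strand claim the same element, only the
  higher-scoring one survives.
* Candidate models shorter than 50 residues are discarded before evidence
  gathering (`min_protein_length`): the shortest known selenoproteins are
  ~80-90 residues, and sub-gene-sized chance ORFs otherwise consume
  evidence checks and occasionally pair a marginal alignment with a chance
  stem-loop.
* Assembled models must begin at an ATG and end at a TAA/TAG, so genes
  truncated by contig edges are not emitted; partial-gene recovery is a
  known limitation.
* The product-to-genome mapper does exact spliced matching (protein- or
  mRNA-level) with GT..AG introns; after a candidate acceptor it requires
  three further residues to match before committing, which keeps the search
  deterministic and linear in practice and assumes exons of at least four
  codons.
* `run_pipeline()` is deterministic given (config, seed): the only
  randomness is the shuffled-database threshold calibration, seeded from
  the config, and report files are byte-identical across reruns.
* Reported problem sizes: the standard 2 Mb benchmark, 1,000-window SECIS
  null, 100 kb Markov recovery and 100 DP oracle instances together run in
  a few minutes on one CPU; they are desk-scale by design.

On Markov parameter recovery: with an order-2 three-periodic coding model,
100 kb of training sequence gives roughly 2,000 observations per
context-phase cell, so the standard error of a single estimated
$\log_2$-probability near $p = 0.25$ is about 0.055 and the maximum error
over all 192 coding parameters is typically 0.15--0.30. Driving the maximum
below 0.05 with margin would need roughly 1.4 Mb. The package therefore
treats ~0.2 as the expected maximum recovery error at 100 kb; the mean
absolute error at that size is ~0.04.

## A worked session

```{r}
library(selenoscan)

sim <- simulate_benchmark(generator_config())        # 2 Mb, 20 genes, seed 42
models <- fit_models_from_truth(sim$genome, sim$truth, k = 5)
calls <- run_pipeline(sim$genome, sim$proteins, sim$ests,
                      pipeline_config(seed = 1, organism = "synthetic"),
                      models, out_dir = "out")
benchmark_metrics(calls, sim$truth)
summarize_families(calls)
plot_calls(calls[calls$status == "confirmed", ])
```

The same functions back the command-line interface
(`inst/scripts/selenoscan simulate | run | report`) for use outside R.

## Known limitations

Single best ORF per focal TGA (no isoforms); no partial genes at contig
edges; type-1-like SECIS topology only (two helices, two loops -- no
type-2 mini-helix); alignment-based family assignment rather than profile
models; the flank-conservation step is a single identity threshold rather
than a motif model; structural scores are not comparable across parameter
settings or to covariance-model scores.
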