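# foldmsa

Structure-informed multiple sequence alignment of protein families, at
desk scale and with every engine built in.

Protein families with a conserved fold but low sequence identity
(< 30%) defeat sequence-only aligners: the conserved β-strands and
α-helices drift out of register, and the variable loops between them
accumulate arbitrary gaps. `foldmsa` aligns such families the way
structure-informed pipelines do — but self-contained, deterministic,
and testable without external binaries, reference databases, or network
access. It is aimed at method developers and at anyone who needs
reproducible structure-aware alignments of modest-sized families
(tens of sequences) in R.

The pipeline: **clean** (greedy identity clustering, CD-HIT-style
shorter-sequence identity convention) → **match** (structures from user
files or pluggable providers; sequences left over are *structureless*;
structures with > 25% unresolved residues are excluded) → **subset**
(permissive clustering, default 30% identity, with collation of small
clusters or *orphan* labelling) → **align** (per-subset iterative
structural alignment: Gotoh affine-gap DP on
`w_seq·BLOSUM62/4 + w_ss·δ(ss)` seeded, then Kabsch superposition with
outlier trimming and a structural proximity term `w_d/(1+(d/d0)²)`,
iterated to a fixed point; progressive profile alignment over an
average-linkage guide tree) → **merge** (profile–profile alignment that
only ever inserts full-height gap columns, so every subset alignment is
reproduced bit-exactly inside the result) → **squeeze** (re-pack the
gap-inflated loop regions between conserved secondary-structure blocks,
leaving block columns untouched).

Quality is measured by the Column Score

```
CS = (1/m) · Σᵢ scoreᵢ ,   scoreᵢ ∈ {0, 1}
```

where a reference column scores 1 only if some query column contains
exactly the same set of (row, residue-index) pairs, and `m` counts the
evaluated reference columns. A synthetic protein-family generator
(conserved H/E blocks, loop-borne indels, identity calibrated by
bisection, ideal backbone coordinates, planted clades, exact
ground-truth alignment) provides the test bed for every stage.

## Worked example

Simulate a family of 8 sequences in 2 clades at ~35% mean identity,
align it end to end, and score the result against the planted truth:

```r
library(foldmsa)

spec <- family_spec(n_sequences = 8, n_clades = 2,
                    target_identity = 0.35, seed = 7)
fam <- generate_family(spec)
write_family_bundle(fam, "fam")          # family.fasta, *.pdb, *.ss.fasta, truth

cfg <- pipeline_config(input = "fam/family.fasta", structures = "fam",
                       output_dir = "fam_out")
res <- run_pipeline(cfg)
print(res$msa)

ref_ann <- annotate_columns(fam$truth$msa, fam$truth$ss)
column_score(res$msa, fam$truth$msa, regions = region_masks(ref_ann))
```

```
msa: 8 sequences x 59 columns
  seq001               QYRRNSMEAKWGNVLPPQKDWGYD-GYTWDDHGMSHSCGLSPSDKVNDSQPLWVCIMEN
  seq002               QYRRNSGPAK--YVLPPQGDVGYDWLYTPDDHGMPHLCKLFPSYKNNDSVQHWGYNMCQ
  seq003               YYCRNWGEGK--YQRSCYPSEQYS-LYTFDNHGTVIRMRLESSYCVNDSILHWKSIMMK
  seq004               QYRRNGGEGK--YQGPAEPDEQYS-LYTFDNHGIQIMMGLEPSNCVNDSILHWQSIMEK
  seq005               SYPAMDVEGT--YVGWLQDDLQRYQQQTGDNQGSWWRWWDMRSAGQRTSVAHILCIRLV
  seq006               SYPACWVEGT--YVQWLQDDLQRDQQCTGDNGGSWWDKWDHGSWGQWTSVNHILQIRKV
  ... and 2 more
Column Score: 0.9492 (56/59 reference columns)
  conserved    CS 1.0000 (m = 38)
  loop         CS 0.8571 (m = 21)
  query: 8 x 59, 17 gaps (3.6%)
```

All 38 conserved-block columns of the planted truth are reproduced
exactly (`conserved CS 1.0000`); the overall score of 0.9492 means 56 of
the 59 reference columns match, with the three misses in loop regions,
where column identity carries little information at this divergence.
Rerunning `run_pipeline(cfg)` in the same output directory skips every
stage whose inputs are unchanged (per-stage JSON manifests under
`fam_out/manifests/`); `fam_out/report.tsv` lists each sequence's fate
(kept / dropped-redundant / excluded-unresolved / subset / orphan /
structureless).

A thin command-line front end is installed at
`system.file("cli", "foldmsa.R", package = "foldmsa")` with
`simulate`, `run`, `evaluate` and per-stage subcommands.

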