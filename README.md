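# spliceclip

Tools for asking, from CLIP-seq and RNA-seq alignments, how an RNA-binding
protein engages 5' splice sites (5'SSs) and what happens to splicing when it
is lost. The motivating biology: some splicing factors bind **unspliced,
weak donors** — sites with poor complementarity to the U1 snRNA 5' end —
and their depletion causes **intron retention** and **cryptic 5'SS usage**
confined to those weak-donor introns.

## What the package computes

Writing the donor 9-mer as positions −3..+6 around the exon|intron boundary
(consensus CAG|GTAAGT), the pipeline's core quantities are:

* **5'SS-anchored signal** — per-base coverage of uniquely mapping,
  sense-strand reads in ±200 nt around each expressed donor, cpm-normalized
  (`10^6 / library size`) and averaged over replicates; the metaprofile
  peak offset locates the protein's cross-link mode (≈30 nt upstream of the
  donor for the factors this analysis was built around).
* **Spliced vs unspliced binding** — for donors of introns >1 kb, reads are
  *spliced* (alignment gap exactly the annotated intron) or *unspliced*
  (contiguous across the boundary, ≥5 nt each side); donors with ≥50 reads
  in ±100 bp and both counts >10 get `log2(spliced/unspliced)`.
* **Target introns** — candidate coverage peaks that overlap between
  replicates, exceed 35 nt, and hold >5 combined reads in a 50-bp window
  around their center, assigned to donors via a [−100, +50) nt window.
* **Splice-site strength** — trained log-odds PWMs: donor 9-mers, acceptor
  23-mers, branch-point 7-mers (best window 18–44 nt upstream of the 3'
  end), scored in bits as `Σ log2 p(base|pos)/background`; two-group
  Wilcoxon rank-sum comparisons.
* **Differential intron expression** — NB Wald test (median-of-ratios
  normalization, trended method-of-moments dispersion) with the published
  prefilters (introns <110 counts excluded; genes <200) and calls
  (introns: padj <0.05, log2FC >0.5; genes: padj <0.01, |log2FC| >1);
  *misspliced* introns are up-regulated introns inside genes with
  log2FC <0.
* **Cryptic (novel) 5'SS events** — junction gaps sharing an annotated
  acceptor but not its donor; kept at >30 reads, inclusion-level difference
  >0.1, and BH FDR <0.01 from per-event Fisher 2×2 tests.

A deterministic **synthetic-data generator** produces a toy genome,
GTF annotation, and pre-aligned CLIP/RNA-seq SAM records with known ground
truth (donor strength classes, spliced fractions, cross-link offsets,
planted intron up-regulation and cryptic donors), so every stage is
testable end to end without downloads or an aligner.

## Worked example

```r
library(spliceclip)

cfg <- pipeline_config(
  sim = simulation_config(seed = 1, n_genes = 12, n_reads_per_library = 20000)
)
res <- run_pipeline(cfg)
str(res$metrics)
```

prints (elided):

```
$ read_categories                  : rRNA 1000, mRNA 17200, genome 1800, unmapped 0
$ ms_snrna_fraction                : num 0.0823
$ junction_donors_kept             : int 9
$ metaplot_peak_offset             : int -30
$ targets_P1                       : int 17
$ target_overlap                   : int 15
$ misspliced_introns               : int 6
$ misspliced_target_fraction_P1    : num 35.3
$ upregulated_vs_unaffected_donor_p: num 0.000534
$ upregulated_median_donor_score   : num 12.5
$ unaffected_median_donor_score    : num 13.9
```

Reading it: the read triage recovers the planted 5% rRNA and 9% snRNA
contamination; the CLIP metaprofile peaks 30 nt upstream of donors, where
the generator put the cross-links; 17 introns carry reproducible peaks for
protein P1, 15 of them shared with P2 (both bind the same weak donors); 6
introns are up-regulated in the knockout inside non-up-regulated genes, all
of them weak-donor targets — hence the misspliced set's median donor score
(12.5 bits) sits below the unaffected targets' (13.9 bits), rank-sum
p = 5.3e-4. With `outdir` set, each stage also writes TSV/BED/SAM/FASTA/GTF
files and a `metrics.json` that is byte-identical across reruns with the
same seed.

Single stages compose the same way without the orchestrator, e.g.

```r
g    <- generate_genome(cfg$sim)
ann  <- generate_annotation(cfg$sim, g)
intr <- extract_introns(ann, g$genome)
clip <- simulate_clip_reads(cfg$sim, g)
junction_ratio_table(clip$reads, intr) |> dplyr::filter(kept)
```

`autoplot()` works on coverage matrices (heatmap), metaprofiles, and DE
results (MA plot); `tidy()`/`glance()` on PWMs, count tables, DE fits and
metaprofiles.

A thin command-line wrapper over the same functions is in
`inst/scripts/spliceclip.R` (`simulate` and `run` subcommands).

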