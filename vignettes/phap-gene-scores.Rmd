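---
title: "Gene-level SNP aggregation for dose-response pharmacogenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level SNP aggregation for dose-response pharmacogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A dose-response GWAS with a few hundred patients cannot survive
genome-wide multiplicity correction. `phapscore` narrows the hypothesis
space twice. First, a *knowledge filter*: only genes on a user-supplied
candidate pharmacogene list are analysed at all, and of those only the
genes with at least one measured SNP are retained. Second, *aggregation*:
each retained gene's SNPs are collapsed into one per-patient score, so
correction is over hundreds of genes rather than thousands of SNPs.

The score for patient $i$ and gene $j$ is

$$\mathrm{pHap}_{i,j} \;=\; \sum_{k=1}^{N_j} -\ln f_{i,j,k},$$

where $N_j$ is the gene's SNP count and $f_{i,j,k}$ is the frequency of
the genotype patient $i$ carries at SNP $k$. The score is a per-gene
"surprisal": 0 when every genotype is the cohort's only one, large when
the patient stacks up uncommon genotypes. Its working assumption is the
rare-variant burden intuition — genes in which extreme-phenotype patients
concentrate low-frequency variation are more likely to modulate the
phenotype. The score is additive over any partition of the SNP set,
non-negative, and strictly increasing as any carried genotype becomes
rarer; these properties are unit-tested.

**Genotype versus allele frequencies.** The defining sentence of the
statistic speaks of genotype frequencies while its symbol reads like an
allele frequency, and the two are not equivalent (a heterozygote's two
alleles factor the term only under Hardy–Weinberg). Both are implemented
— `mode = "genotype"` (default, matching the operational description) and
`mode = "allele"` — and every output records which was used. No claim is
made that either reproduces the original computation bit for bit.

**Frequency estimation.** Frequencies are estimated in-cohort over
non-missing calls, with no leave-one-out and no pseudocount. This makes
every observed genotype's frequency at least $1/n$, so in-cohort scores
are always finite. Externally supplied frequency tables can contain
zeros; those raise an error unless `freq_floor` clamps them, a deliberate
speed bump rather than silent imputation. The patient's own genotype is
included in the estimate: at cohort sizes near 200 the bias is
$O(1/n)$ and identical across patients, and leave-one-out would make the
score depend on cohort order.

**Missing genotypes** contribute zero terms. Any imputation would need a
model the pipeline does not otherwise require; the per-score tally of
skipped calls (`n_missing`) keeps the effect auditable. The upstream I/O
preserves missingness exactly — policy is decided only here.

**Log base** is natural (scores in nats). Any base change is a linear
rescale of all scores, and the regression t, the two-sample t, the
logistic ranking and the AUROC are all invariant to affine rescaling of a
feature; a test asserts the regression p-value is unchanged under
rescaling.

## The pipeline parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_r2` | 0.2 | r² | LD ceiling for the SNP panel; pairs above it are redundant for burden-style aggregation |
| `window_bp` | 5000 | bp | flank added to each gene body when assigning SNPs; regulatory variants sit near, not in, genes |
| `alpha` | 0.05 | — | family-wise error rate; Bonferroni over the features actually tested |
| `low_threshold` | 3 | mg/day | inclusive low-dose class cutoff |
| `high_threshold` | 7 | mg/day | inclusive high-dose class cutoff |
| `folds` | 10 | — | cross-validation folds |
| `null_reps` | 100 | — | random-gene-set draws; empirical-p floor 1/101 |

**LD pruning** is a greedy sweep in (chromosome, position, id) order: a
variant is kept iff its r² with every already-kept same-chromosome
variant is at most `max_r2`. Only the ceiling is specified by the method;
the sweep order is this package's choice because it is deterministic and
the standard one. r² is the squared Pearson correlation of dosage vectors
(composite LD) over pairwise-complete samples — no phasing, no reference
panel: the pruning cohort is the analysis cohort, and that choice is
documented rather than assumed away. A pair with fewer than two complete
observations or a constant vector is "not computable" and treated as
independent (r² = 0), logged, never fatal.

**Windowed mapping** converts VCF 1-based positions to 0-based once, at
the mapping boundary, and assigns variant $v$ to gene $g$ iff
$\mathrm{pos}_0(v) \in [\mathrm{start}-w,\ \mathrm{end}+w)$ in BED
half-open coordinates. "Within $w$" has no published edge convention;
inclusivity at exactly $w$ below the start is chosen and unit-tested at
both edges (0-based 5000 in, 4999 out, for a gene starting at 10000 with
$w = 5000$). SNPs matching several genes are duplicated into each;
candidate genes with no measured SNP are dropped from all downstream
analyses. Override entries attach a named variant to a named gene
unconditionally — the mechanism for keeping a tag SNP in perfect LD with
a causal variant attached to its gene.

**Association screens** are ordinary least squares of dose on one feature
at a time, two-sided t on the slope with $n-2$ df, no covariates —
deliberately reproducing the univariate design of the original analyses.
A perfect fit reports the smallest positive double rather than 0 and is
flagged. Bonferroni uses the number of features actually tested (skipped
zero-variance features are recorded, not counted). The gene-level
corrected cutoff of $10^{-3}$ quoted in the source narrative does not
equal $0.05/228$; no alpha is reverse-engineered from it — the package
always computes $\alpha/m$ and exposes `alpha_corrected_override` for
anyone wanting the quoted number.

**Extreme-dose discovery** uses the classic pooled-variance two-sample
Student's t (the named test), with `welch = TRUE` available since the
equal-variance assumption is a choice, not a datum. Thresholds are
inclusive exactly as printed (≤ 3, ≥ 7). The strict set is the
Bonferroni survivors; the nominal set is raw p ≤ 0.05 and always contains
the strict set.

**Classification** fits logistic regression by IRLS with a ridge penalty
of $10^{-6}$ on non-intercept weights. Pure maximum likelihood diverges
under the quasi-separation that a strong feature in a 60–180 patient
cohort produces routinely; $10^{-6}$ is far below any statistically
visible shrinkage (the ridge-0 fit matches `glm` to $10^{-6}$ on
well-conditioned data, unit-tested) yet keeps the optimum finite.
Convergence is on penalized deviance with step-halving. Folds are
stratified by class with a seeded shuffle: with ~10–20 positives out of
181, unstratified folds would regularly contain one class. The ROC is
built from the pooled out-of-fold probabilities, not from averaging ten
per-fold curves: "average performance" is ambiguous, and pooling is
deterministic, uses every sample exactly once, and makes AUROC equal the
tie-corrected Mann–Whitney statistic (asserted against pair enumeration).
The empirical p-value compares the observed AUROC with classifiers
trained on `n_features` genes drawn without replacement within each of
$B$ independent draws (draws are independent across replicates — whether
the original procedure reused genes across replicates is unknowable from
the narrative, and independent draws are the cleaner null). The add-one
formula $(1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1+B)$ never returns
zero and has floor $1/(B+1) = 1/101$ at the default $B = 100$, which is
why such models report "p < 0.01" and never less.

## The synthetic cohorts

The generator emulates exactly the structure the pipeline consumes:
diploid genotypes under Hardy–Weinberg at per-SNP MAFs drawn uniformly
from `maf_range`; optional local LD by letting each successive SNP copy
its gene-neighbour's haplotype allele with probability `ld_rho` (genes
independent, so the pruner is exercised within genes only); genes on
disjoint 100-kbp intervals, ten per synthetic chromosome; and dose
$= \mathrm{baseline} + \sum \beta \cdot (\text{minor-allele burden}) +
\mathcal N(0, \sigma)$, floored at 0.5 mg/day.

Defaults state a world once: 181 patients (the reference cohort size), 50
candidate genes with 4–12 SNPs each (scaling the 228-gene / 3,856-SNP
panel to desk size), common-variant MAFs 0.05–0.5, baseline 5 mg/day and
noise SD 2 mg/day — a typical maintenance-dose distribution whose ≤ 3 and
≥ 7 mg/day tails are both populated. `effect_beta_for_variance` sizes a
planted $\beta$ so one gene explains a chosen dose-variance share (0.3
echoes the share attributed to the major dose-determining gene in this
drug's literature). Planted effects act through minor-allele **burden**,
not through the pHap score itself, so recovery by the score is a genuine
test and not circular. Because the dose formula is taken literally, a
planted effect shifts the population mean by $\beta \,\mathbb E[\text{burden}]$;
test configurations compensate the baseline so the dose distribution
stays centred — the generator itself does not silently re-centre.

What a green test does **not** establish: the generator has no population
structure, no genotyping error, no missingness mechanism, no
haplotype-block realism (LD is first-order Markov within genes), and no
dominance or epistasis. Results on real cohorts additionally depend on
the quality of the external gene ranking, which this package consumes but
does not produce. The original cohort's headline numbers (its AUROCs and
table p-values) depend on genotypes that are not redistributable and are
therefore not reproduction targets; the acceptance suite instead verifies
the input-free printed threshold, oracle equivalence of the score,
pruner post-conditions, statistical calibration under the null, planted-
effect recovery, classifier sanity, and byte-level determinism.

## Numerical corner cases

- Dosage codes outside {0, 1, 2, NA}, multi-allelic VCF records and
  non-diploid calls are hard errors at the boundary — multi-allelic
  splitting would silently distort frequency estimates.
- `0 \cdot \log 0` in allele mode is masked before the log is taken, so
  an unobserved allele cannot poison a score it does not contribute to.
- Zero pooled variance in the t test returns $t=0, p=1$ for equal means
  and the machine-minimum p for unequal means, both flagged paths.
- Ties in classifier scores move the ROC diagonally; AUROC counts tied
  pairs one half, so the trapezoid and rank forms agree exactly.
- Fold assignment lowers $k$ with a warning when a class has fewer than
  $k$ members; leave-one-out per class is the limit.

## Known limitations

Scores are phase-blind (a compound heterozygote and a double heterozygote
in cis score identically); frequencies are unstratified, so population
structure inflates scores of ancestry-informative genes; the regression
screens carry no covariates by design; and the empirical p-value's
resolution is $1/(B+1)$ — claims below it require more draws.
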