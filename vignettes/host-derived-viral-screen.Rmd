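---
title: "Screening protein families for host-derived viral proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein families for host-derived viral proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virhijack)
```

## The problem

Viruses that infect animals occasionally acquire coding sequence from their
hosts. Long after the event, the acquired protein typically survives in the
viral genome in a simplified form: shorter overall, with fewer domains, and
with much shorter linkers between and around the domains. `virhijack`
implements a desk-scale version of the screen that finds such candidates in
cross-taxa protein families — families that contain both viral and metazoan
members — and quantifies the architectural simplification of the viral
copies.

The screen has three stages, applied in order:

1. **Family filtering** reduces raw cross-taxa families to an analysis set.
2. **Tree topology** asks whether the viral members of each family look
   like a small number of acquisition episodes.
3. **Architecture statistics** compare viral and metazoan members of the
   surviving families: protein length, domain counts, and linker lengths.

A synthetic-cohort generator with planted effect sizes stands in for the
database inputs, so every stage is testable end to end without downloads.

## Filtering cascades

Two cascades are provided, matching the two kinds of cross-taxa family.

For *sequence clusters* (UniRef-style): keep families with at least
`min_cluster_size = 2` members, then require at least one viral member,
then at least one metazoan member.

For *domain families* (Pfam-style): require at least one viral and at
least `min_metazoan = 2` metazoan members; remove families whose viral
member fraction exceeds `structural_viral_fraction = 0.95` (these are
viral structural elements — Env, Coat, Capsid — with incidental cellular
members, not host-derived sequence); remove families matching the
exclusion list. The shipped exclusion list covers the replication
machinery whose evolutionary history involves repeated exchange in both
directions (polymerases, exo/endonucleases, helicases, tRNA synthetases,
primases) and the GFP family, which is a laboratory contamination in
sequence databases. Exact database identifiers are release-dependent, so
the list is expressed as editable case-insensitive name patterns
(`inst/extdata/excluded_families.tsv`). By default the >95%-viral rule is
applied to all families; `structural_name_pattern` restricts it to
families whose name matches (e.g. `"env|coat|capsid"`) for users who
prefer the narrower reading.

Viral fraction is computed over member counts, not species counts,
because the selection statistic downstream is phrased as the ratio of
viral proteins to all proteins in the family.

Every stage records a trace row (`n_in`, `n_out`, removed ids); traces
always reconcile and filtering is idempotent.

## Tree topology: viral clusters and normalized depth

Each family tree is a rooted, leaf-labeled tree whose leaves are protein
ids (Newick input; either already rooted or midpoint-rooted when branch
lengths are available). All depth statistics are **topological**: the
depth of a node is the number of edges from the root, and branch lengths
are ignored. With this convention, a leaf 9 edges deep in a tree whose
deepest leaf is 19 edges deep has normalized depth 9/19 ≈ 0.474 — the
convention was chosen over node counting precisely because it reproduces
such worked ratios; node counting would shift both numerator and
denominator by one.

A **viral cluster (VC)** is a maximal sub-tree all of whose leaves are
viral: a node whose descendant leaves are all viral and whose parent has
at least one non-viral descendant. A lone viral leaf with a non-viral
sibling is a VC of size 1. VC leaf sets partition the viral leaves; both
the partition and maximality are asserted on every run and checked
against an exhaustive per-node oracle in the tests. The **VC depth** is
the depth of the VC's *root node* (not its leaves) over the maximum leaf
depth — the only reading under which a VC can be shallower than its
member leaves. The **condensation factor** is the number of viral
proteins divided by the number of VCs; each VC is read as one candidate
acquisition episode, so a high condensation factor means many closely
related viral sequences from few episodes.

A family is **selected** as a host-to-virus candidate by two clauses
combined with AND (alternatives within each clause with OR):

* *marginal viral presence*: viral fraction ≤ `max_viral_fraction`
  (default 0.05, inclusive — the boundary case is kept, and the threshold
  is configurable because usage varies between ≤ and <), OR at most
  `max_viral_count_override = 2` viral proteins in total;
* *clustered viral leaves*: at most `max_vc_simple = 2` VCs, OR at most
  `max_vc_condensed = 10` VCs with condensation ≥ `min_condensation = 3`.

The clauses are ANDed because they act as sequential filters: first the
family must be overwhelmingly cellular, then its viral leaves must be
clustered. Note that a family with, say, 10 viral members out of 146
(6.8%) in 2 VCs fails the first clause under the defaults even though its
viral leaves are perfectly clustered; thresholds are exposed precisely so
users can trade off such cases. Ties for the deepest viral leaf are
reported as the full list of leaves attaining the maximum.

## Architecture: TAIL, IDOL, and internal-domain loss

Each protein with at least one domain hit is decomposed into an N-tail,
the ordered domain segments, the inter-domain linkers (IDOLs), and a
C-tail, using 1-based inclusive amino-acid coordinates. Segment lengths
always sum to the protein length; this conservation identity is asserted
on every decomposition. Overlapping raw hits are resolved greedily by
descending score (ties: longer hit, then smaller start), with nesting
treated as overlap; the greedy result equals the exhaustive
best-priority maximal compatible subset, which the tests verify by
enumeration.

* **TAIL** (per protein) is the mean of the two terminal segments,
  zeros included. The mean — not the sum — is the definition used
  throughout; summing would double the reported scale.
* **IDOL** (per protein) is the mean inter-domain linker length, and is
  undefined (`NA`) for single-domain proteins: absence is a value, not an
  error. IDOL statistics therefore cover only proteins with ≥ 2 domains.
* Proteins with no domain hits are excluded from architecture statistics
  with a logged count, since their decomposition is undefined.

**Internal-domain loss** compares a viral and a host architecture (ordered
domain-id lists). A loss is called only when the viral list embeds into
the host list as an ordered subsequence with both flanks anchored — the
first and last domains must agree — so that only internal domains are
missing while flanking order is preserved. The embedding is greedy
leftmost between the anchored flanks; with repeated domain ids this is
one canonical embedding among possibly several, a deliberate
simplification documented here. The call is anti-symmetric by
construction: swapping a longer viral architecture into the host slot
yields no call.

Family summaries report per-class (virus, metazoa) means and medians of
length, domain occurrences (repeats counted), distinct domains, TAIL and
IDOL, plus metazoan/viral ratios and a `viral_shorter` flag. Means are
per protein; a per-species weighting was considered and rejected as the
default because species annotations in real inputs are far less reliable
than protein records (the `species` column is carried so users can
aggregate differently).

## Statistical tests

* `ks_two_sample()`: two-sample Kolmogorov–Smirnov D (maximum ECDF
  distance), asymptotic p at effective n = n_a·n_b/(n_a+n_b); an exact
  small-sample mode is available. The asymptotic default matches the
  sample sizes the screen targets (10³–10⁵).
* `hypergeometric_tail()`: P[X ≥ k], evaluated on the stable
  `lower.tail = FALSE` path.
* `sign_enrichment()`: the "viral shorter in k of n families" test. The
  natural null is a fair coin per family, so the default is a one-sided
  binomial sign test with p0 = 0.5; a hypergeometric mode (finite pool of
  family outcomes) is available behind an argument because the urn for
  that parametrization is not uniquely determined — the package reports
  the parametrization used rather than guessing silently.
* `paired_t()`: classical paired t on per-family class means, with a
  degenerate-input error when the differences have zero variance (and
  the conventional t = 0, p = 1 when all differences are exactly zero).
* `ecdf_table()`: cumulative fraction on an integer grid, for
  linker-length curve exports.

No multiple-testing correction is applied by default; the handful of
headline comparisons are reported as-is, and users can apply
`p.adjust()` to the `tests.tsv` output if they extend the battery.

## The synthetic cohort generator

`cohort_params()` + `generate_cohort()` emulate the statistical structure
the screen assumes, not sequence evolution:

* Each family has a multi-domain **host architecture** (distinct ordered
  domains; lengths ~ Normal, floored at 20 aa, shared by both classes —
  domain lengths themselves are *not* planted to differ, mirroring the
  observation that domains keep their length while linkers shrink).
* **Metazoan proteins** realize the architecture with linkers from the
  metazoan model; **viral proteins** drop each internal domain with
  `domain_loss_prob` (flanks always retained) and redraw all linkers from
  the viral model.
* **Defaults are the reported corpus scales**: TAIL means 85 vs 14 aa,
  IDOL means 67 vs 30 aa; host `n_domains_mean = 4.6` with
  `domain_loss_prob = 0.65`, which reproduces the 4.6 → 2.9 average
  domain-count contrast (2 retained flanks + 2.6 internal × 0.35 ≈ 2.9).
* **Linker lengths are geometric** by default (`rgeom` with mean m has
  p = 1/(m+1)): discrete, mode at zero, heavy at short lengths, matching
  observed linker histograms. A discretized gamma (shape 2) is offered as
  a smoother alternative.
* **Trees** plant exactly `n_viral_clades` viral clades: a Yule (random
  split) or caterpillar metazoan backbone, with each viral clade grafted
  as the sister of a distinct metazoan leaf. Every grafted clade's parent
  therefore has a metazoan descendant, so maximal viral-cluster detection
  must return exactly the planted count — an exact, not statistical,
  recovery contract.
* Ground truth (planted clade counts, architectures, per-protein lost
  domains, linker means) is written to a separate `truth.json`, never
  embedded in the data files, so the pipeline under test cannot cheat.
* Fixed seed ⇒ byte-identical output.

What the generator does **not** emulate: sequence-level evolution,
alignment or tree-estimation error, database redundancy, fragment
annotations, or correlated linker/domain lengths. Passing tests on
planted cohorts therefore demonstrate that the pipeline's measurements
invert the generative model faithfully — they do not validate the
biological conclusions on real database snapshots, whose headline numbers
(counts of surviving families, exact means, p-value bounds) are
database-release-dependent and out of scope here.

```{r example}
params <- cohort_params(n_families = 10,
                        members_per_family = c(metazoa = 12, virus = 3),
                        tree_model = list(n_viral_clades = 1,
                                          topology = "yule"),
                        seed = 7)
cohort <- generate_cohort(params, file.path(tempdir(), "demo"))
cfg <- run_config(members = cohort$paths$members,
                  domains = cohort$paths$domains,
                  trees_dir = cohort$paths$trees,
                  family_type = "domain",
                  thresholds = selection_thresholds(max_viral_fraction = 0.25),
                  out_dir = file.path(tempdir(), "demo_out"), quiet = TRUE)
report <- run_pipeline(cfg)
report$viral_shorter_fraction
report$tests[, c("comparison", "statistic", "p_value")]
```

## Numerical and design notes

* Degenerate inputs: single-leaf trees have no defined normalized depth
  (error); zero-hit proteins have no decomposition (error at the
  operation level, exclusion with a count at the pipeline level);
  zero-variance paired differences are a degenerate-input error unless
  identically zero.
* Fragments: membership tables accept an optional boolean `fragment`
  column; fragment records are carried as-is (no length normalization is
  attempted, since no principled correction is available without the
  full-length reference).
* Coordinates are 1-based inclusive throughout, the domain-annotation
  convention; `start = 0` is rejected at parse time.
* Problem sizes in the shipped tests were chosen to keep the whole suite
  around half a minute while leaving the statistical contracts
  well-powered: 1,000 random trees (≤ 20 leaves) for the viral-cluster
  oracle, 10,000 proteins for the conservation identity, 500 sample pairs
  for the KS oracle, and cohorts of 40–100 families elsewhere.
* The command-line entry point (`inst/cli/hijack-scan.R`) is a thin
  wrapper over `generate_cohort()` and `run_pipeline()`; the package
  functions are the primary interface.

## Known limitations

* The selection thresholds interact: families whose viral fraction
  slightly exceeds the default 5% are rejected even when their viral
  leaves form a single clean cluster. This is deliberate — thresholds are
  data-set calibrations, not constants of nature — and all of them are
  arguments.
* Internal-loss detection with repeated domain ids commits to one
  canonical (greedy leftmost) embedding.
* The hypergeometric variant of `sign_enrichment()` requires the caller
  to define the pool; no default urn is imposed.
* Midpoint rooting requires branch lengths; trees without them must
  arrive rooted.
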