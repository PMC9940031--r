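---
title: "synthzoo: methods, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synthzoo: methods, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What the package is

synthzoo is a metadata-driven zoo of generative models for medical images.
Every model is described by one entry in a single JSON registry; the entry
carries everything needed to find the model (keywords, performance metrics),
run it (package location, entry script, generate method, declared image
size and latent dimension), and cite it (title, modality, training dataset,
license, date). On top of the registry sit five capabilities: keyword search
with AND/OR/XOR operators and metric-based ranking; a lazy executor that
resolves, imports, and runs model packages in seeded batches; an evaluation
suite built around the Fréchet inception distance (FID) and the FID ratio
rFID; a latent-space explorer modelled as an immutable state machine; and a
contribution workflow that validates, smoke-tests, registers, archives, and
publishes new model packages through a pluggable, offline-safe publisher.

```{r, eval = FALSE}
library(synthzoo)
zoo_files <- build_fixture_zoo(tempfile(), seed = 7)
zoo <- model_zoo(zoo_files$registry_path)
find_model(zoo, c("patches", "mammography"), "AND")
res <- find_models_rank_and_generate(zoo, "mammography", metric_key = "FID",
                                     order = "ascending", num_samples = 8,
                                     seed = 7)
```

## The registry contract

The registry is a single JSON object keyed by model id. Ids follow the
pattern `^[0-9]{5}(_[A-Z0-9]+)+$` — a five-digit zero-padded ordinal plus
uppercase tokens, e.g. `00001_DCGAN_MMG_MASS`. Each value has exactly three
sections: `execution` (how to run the model), `selection` (how to find and
compare it), and `description` (what it is). The shipped
`inst/schema/registry.schema.json` documents the full field inventory;
`validate_metadata()` enforces the same rules in code and returns violations
rather than raising, so loaders can aggregate them. Two deliberate
asymmetries: non-canonical ids are *warnings* at load time but *errors* at
contribution time (forward compatibility for registries written by newer
tools), and a duplicated id in the byte stream resolves last-wins with a
warning, matching how streaming JSON parsers treat repeated keys.

Registry updates are file edits, never network calls; `register_and_package()`
appends atomically (copy, write, roll back on failure) and refuses duplicate
ids, which mirrors a pull-request-style append-only update model.

## Search and ranking semantics

`flatten_metadata()` collects, depth-first, every string leaf and every key
name of an entry, lowercased. Numeric leaves are excluded — a query for
"80.51" should not match a model whose FID happens to print that way — but
their key names (e.g. `fid`) remain searchable. A query value matches a
model when it is a case-insensitive *substring* of any flattened string;
substring rather than exact matching is what lets "mammography" find a
model whose title says "Mammography". With k matching values out of m
queried, `AND` requires k = m, `OR` requires k ≥ 1, and `XOR` — generalized
k-ary — requires exactly k = 1, the only consistent extension of two-input
XOR. These semantics give the algebra the tests assert: AND- and
XOR-results are subsets of OR-results, and all three coincide for
single-value queries.

Ranking resolves a dotted path (e.g. `FID`, `downstream.dice`) inside
`selection.performance`. Models lacking the metric are appended, flagged,
in registry order rather than dropped, so a ranking UI always shows the
full candidate set. Ties break by id, ascending, in both sort orders, which
makes rankings total and deterministic. FID is in the package's
lower-is-better set, so its default order is ascending.

## The executor and its seeding contract

A model package is a directory (or archive) containing an entry script
named `model.R` that defines the generate function named in the metadata,
with the standardized signature

```r
generate(model_file, num_samples, save_images, output_path, seed, ...)
```

plus model-specific arguments such as `input_latent_vector`, `condition`,
or `input_image_dir`. Resolution is lazy and cached: constructing the
facade does no I/O, searching loads only the registry, and a model package
is fetched (through a pluggable fetcher, so tests can spy on it and remote
hosting can be added without touching the executor) only when that model
first generates. Local directories are used in place; archives are
extracted once under `cache_dir/<model_id>` and reused.

Generation proceeds in `ceiling(num_samples / batch_size)` chunks. The
reproducibility contract has two halves: the executor passes each batch the
request seed plus the batch's global start index, and the entry script must
derive sample j of a batch from `seed + j - 1`. Together these make the
output an elementwise function of (request seed, global sample index), so
the same seed yields bit-identical output for *any* batch size — asserted
directly in the tests. A bare per-batch seed without the within-batch
offset would not have this property. When saving to disk, each batch is
written and released before the next is generated, so peak resident samples
never exceed one batch; files are named `{model_id}_{index:06d}.png`
(masks as `_mask.png` siblings) and a `manifest.json` records files, model
id, and seed.

Dependency checking probes namespace presence only. Version specifications
are recorded in the report but not enforced: without a full resolver,
refusing to run over a version string would produce false negatives far
more often than it would prevent real breakage.

## FID, the real–real lower bound, and rFID

Two image sets are compared by fitting a Gaussian to the feature matrix of
each — column means μ and *unbiased* (n − 1) sample covariance Σ, the
estimator used by the dominant FID implementations — and evaluating the
Fréchet (Wasserstein-2) distance

$$ d^2 = \lVert \mu_X - \mu_Y \rVert^2 +
   \operatorname{tr}\!\left(\Sigma_X + \Sigma_Y -
   2 (\Sigma_X \Sigma_Y)^{1/2}\right). $$

The matrix square root is evaluated through the symmetric reformulation
$\operatorname{tr}\,(\Sigma_X^{1/2} \Sigma_Y \Sigma_X^{1/2})^{1/2}$, which
is mathematically identical for symmetric PSD covariances but needs only
symmetric eigendecompositions: no complex arithmetic can arise, and
eigenvalues driven slightly negative by rounding are clamped at zero. If
the result is still non-finite (pathologically singular inputs), both
covariances are jittered with $10^{-6} I$ and the computation retried; a
result within $10^{-6}$ below zero is clamped to 0. The oracle tests pin
this implementation to the closed form for diagonal Gaussians up to
dimension 10 at $10^{-8}$.

Because FID depends on the feature space, the extractor is a contract —
`id`, expected input, `apply(images) -> n × d matrix` — and the extractor
id is carried in every report, so results are never separated from the
representation that produced them. The default extractor is a deterministic
seeded random projection of 8 × 8 average-pooled grayscale pixels to d = 64
dimensions (`toy-rp-{seed}-{d}`). It is a genuine, if simple, feature map:
linear in pooled intensities, hence sensitive to brightness and coarse
structure shifts, and it makes the entire metric stack testable offline.
Pretrained backbones (natural-image- or radiology-pretrained networks) plug
in through the same contract; nothing in the evaluation code is specific to
the toy map.

Pixel handling is fixed once: in-memory images live on the 8-bit 0–255
scale; `normalize_images()` offers bit-depth scaling (divide by 255) and
dataset min–max scaling (a constant dataset maps to zeros); resizing to an
extractor's expected input is bilinear and antialiased, applied after
normalization, with grayscale replicated to three channels when an
extractor expects RGB. Normalization is applied to both sets being
compared.

FID between two disjoint halves of the *real* set (FIDrr) estimates the
variation intrinsic to the real data and is the empirical floor for any
real-vs-synthetic FID (FIDrs) on that dataset. `fid_lower_bound()` uses a
single seeded shuffle-and-split into halves of sizes ⌊n/2⌋ and ⌈n/2⌉ —
one split, not an average over repeats, with the seed recorded, so the
quantity is cheap and exactly reproducible; averaging over splits would
reduce variance but hide the dependence on the split in an unreported
expectation. The FID ratio

$$ \mathrm{rFID} = 1 - \frac{\mathrm{FID}_{rs} - \mathrm{FID}_{rr}}{\mathrm{FID}_{rs}} $$

expresses FIDrs in units of the real data's own variation: near 1 means
the synthetic set is about as far from the real data as the real data is
from itself. Under FIDrs ≥ FIDrr it lies in [0, 1]; empirical violations
(possible at small n, where the split FID fluctuates) are clamped to 1 and
flagged. The bundled `fid_benchmarks()` table carries published (FIDrr,
FIDrs) pairs for a 21-model zoo, including a 16-model cross of extractor
pretraining domain × normalization setting; the worked examples reproduce
the published ratio column from these pairs, and across the whole cross
table the recomputed rFID never reaches 0.7 — most of a model's FID is
*not* explained by real-data variation, which is exactly why reporting
FIDrr and rFID alongside FIDrs matters.

## The latent explorer

Exploration is a headless state machine over an immutable state: a latent
vector z of the model's declared dimension d, drawn standard-normal from a
seed, and ⌈d/n⌉ sliders, each governing n consecutive dimensions. Slider
values initialize to the mean of their group — the one scalar summary that
is exact when a group was last set through a slider and unbiased for a
fresh draw. `set_slider()` writes one group, `reseed()` redraws z (and
makes the redraw the new reset target), `reset_state()` restores the last
seeded z, and `render_state()` generates one sample with
`input_latent_vector = z`. Fixture models render a *pure* function of z
when a latent vector is supplied (additive noise is only drawn when the
model samples z itself), which is what makes
`render(reset(edit(s))) = render(s)` hold byte-for-byte and keeps a GUI
binding trivially testable without a display.

## What the fixtures emulate — and what they do not

`build_fixture_zoo()` writes four procedural model packages — a
noise-to-image blob generator (64 × 64, d = 16), an ellipse-plus-mask
generator, a class-conditional blob/grating generator, and an
intensity-inverting image-to-image translator — plus a registry that
validates cleanly. `synth_image_set()` draws from the same blob
distribution with an optional intensity shift and class mix, seeding image
i with `seed + i − 1`, the same per-sample contract the models follow; a
fixture model is therefore distribution-matched to these sets by
construction, which is what the evaluation ordering tests exploit: at 200
images per set, the split FID of the real set is far below the FID against
a 64-gray-level-shifted set, and the matched model's rFID is near 1 while
the shifted model's is near 0.

These fixtures exercise every interface contract (latent input, masks,
labels, translation, seeding, archives) but are not medical images: they
have none of the texture statistics, acquisition artifacts, or
inter-patient variability of mammography or endoscopy data, and the toy
extractor is far weaker than a pretrained CNN. Passing tests therefore
certify the *machinery* — metric implementation, determinism, contracts —
not any claim about real-data FID magnitudes, which depend on hosted model
weights and restricted datasets outside this package's scope.

## Problem sizes and other fixed choices

Test and evaluation problem sizes are chosen at desk scale: 64 × 64 images,
200 images per set for the ordering checks, d = 64 toy features. These are
large enough for the FID orderings to be stable across seeds by a wide
margin (the measured gap is orders of magnitude, not percent) and small
enough that the full suite runs in seconds. Default generation batch size
is 32; output is 8-bit PNG, grayscale for one channel and RGB for three,
the smallest lossless common denominator. Model archives are `.tar.gz`
written with deterministic member order via R's internal tar, and `.zip`
archives are accepted on the resolve side. License file and requirements
manifest are warnings when absent from a contribution, errors only under
strict validation.

## Known limitations

Model code is imported and executed without sandboxing — registry
provenance (archives with recorded checksums, append-only updates) is the
mitigation, not process isolation. The dependency probe does not compare
versions. Search has no fuzzy or semantic matching and no persisted index;
numeric leaves are not searchable as strings. The publisher contract ships
only with the local filesystem implementation; network deposition backends
must be supplied by the user. FIDrr uses one split rather than a
split-average, and evaluation assumes both image sets fit in memory as
lists of arrays.
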