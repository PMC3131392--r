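# islandassembly

Tools for asking whether ecological interactions — rather than dispersal
limitation — structured a community assembled by inter-island
colonization. Written for evolutionary biologists working on island
radiations where speciation is overwhelmingly allopatric and tied to
over-water dispersal, and where per-island diversity is too low for the
standard community-phylogenetics toolkit.

Three complementary analyses are provided, each runnable end to end at
desk scale with packaged fixtures or synthetic data:

1. **Colonization null model.** A stochastic simulator of inter-island
   colonization: a random seeding (uncounted), then events drawing a
   source uniformly from occupied islands and a recipient with
   probability ∝ *d*⁻ᵅ (inter-shore distance *d*, kernel exponent α;
   α = 1 and α = 2 are the conventional settings). Arrivals on occupied
   islands count as events — these are the "failed" colonizations the
   model exposes — until *K* distinct islands are occupied. The tail
   P-value compares the replicate event counts against the minimum
   number of events the observed occupancy requires
   (`min_colonization_events()`: distinct populations − 1). With equal
   distances the expected count has the closed form
   Σₘ₌₁^(K−1) (n−1)/(n−m), used as an analytic oracle.

2. **Overdispersion of sympatric pairs.** The statistic
   Δ = A{dᵢⱼ : sympatric pairs} − A{dᵢⱼ : allopatric pairs}, with A the
   mean or median, on a patristic or trait-difference matrix. The null
   redraws the sympatry assignment as uniformly random disjoint pairs;
   alongside the Monte-Carlo test, an exact test enumerates the full
   configuration space (13,860 configurations for 12 terminals, 3
   pairs). Pagel's λ (likelihood-ratio test vs χ²₁) estimates
   phylogenetic signal in the trait.

3. **Niche overlap.** Schoener's *D* = 1 − ½Σ|p_{X,i} − p_{Y,i}| and
   Hellinger-based *I* = 1 − ½Σ(√p_{X,i} − √p_{Y,i})² on normalized
   suitability rasters, minimum-training-presence thresholding, and the
   background-similarity randomization with a pluggable niche-model
   fitter (a simple climate-envelope scorer ships as the default).

The packaged fixtures are the island occupancy and skull-length tables
of the Philippine *Crocidura* (shrew) radiation — nine species across
five Pleistocene Aggregate Island Complexes and three oceanic islands,
with exactly three sympatric species pairs.

## Worked example

Body-size overdispersion on the packaged skull table (12 island
populations, mean condylo-incisive length in mm; three sympatric pairs):

```r
library(islandassembly)

skulls <- load_fixture("table3_skulls")
pairs  <- load_fixture("sympatric_pairs")
m <- trait_difference_matrix(skulls)

delta_stat(m, pairs[, 1:2], "mean")
#> [1] 1.746349
permutation_test(m, pairs[, 1:2], replicates = 2000, seed = 42)
#> Dispersion permutation test (mean aggregator, 3 sympatric pairs)
#>   observed = 1.7463; one-tailed P = 0.0085 (corrected 0.008996) from 2000 randomizations
```

Sympatric species differ in skull length by 1.75 mm more, on average,
than allopatric ones, and fewer than 1% of random sympatry assignments
do as well: body size is overdispersed among co-occurring shrews. (The
exact enumeration over all 13,860 assignments gives P = 0.00866;
`exact_test()` reproduces it.)

The colonization side, on a synthetic six-island line system:

```r
min_colonization_events(fixture_occupancy("archipelago"))
#> [1] 10

sys <- random_island_system(6, "line", scale = 20)
sim <- simulate_colonization(sys,
  colonization_config(target_islands = 5, exponent = 2,
                      replicates = 10000, seed = 42))
sim
#> Colonization simulation: 10000 replicates, K = 5 of 6 islands, alpha = 2
#> Events per replicate: mean 9.32, median 8, range [4, 48]
colonization_pvalue(sim, observed_min = 5)
#> [1] 0.2061
```

Occupying 5 of these 6 islands took 9.3 events on average under the
inverse-square kernel; about 21% of replicates managed it with 5 or
fewer, so on *this* geometry a minimum-event history would not be
surprising. (The real Philippine inter-shore distances were never
published; analyses of that system need a user-supplied matrix.)

The methods vignette (`vignettes/island-community-assembly.Rmd`) gives
the models, assumptions, parameter meanings and numerical choices in
full.

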