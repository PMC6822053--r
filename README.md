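# respguild

Response-guild analysis of ecosystem-function resilience from long-term
population monitoring data.

## The problem

When several species deliver the same ecosystem function (pollination,
provision of larval biomass to insectivorous birds, the aesthetic value of
seeing butterflies), the resilience of that function under environmental
change depends on whether the functionally important species rise and fall
*together*. Species whose populations respond synchronously to the same
drivers form a **response guild**; if most of a function's delivery is
concentrated in one guild, a bad run of years for that guild depresses the
whole function, whereas functionally important species spread across guilds
stabilize it through the statistical-averaging ("portfolio") effect.

`respguild` is for ecologists with long-term, multi-species abundance index
series (national monitoring schemes, collated transect counts) who want to
quantify that risk. From a species × year table of log abundance indices it:

1. computes **interannual changes** Δᵢ(t) = xᵢ(t) − xᵢ(t−1) of the
   standardized log index, and the pairwise Pearson correlation rᵢⱼ of those
   changes over complete pairs of years;
2. transforms correlation into a **population-dynamics distance**
   dᵢⱼ = 1 − rᵢⱼ (0 = perfectly synchronous, 1 = uncorrelated,
   2 = perfectly opposite) and clusters it hierarchically; cutting the
   dendrogram at chosen resolutions allocates species to response guilds;
3. scores each species' functional role with **production functions** built
   from trait data: relative national density D = O·A / max(O·A), larval
   biomass B = D·L / max(D·L), wildflower outcrossing pollination
   P = D·M / max(D·M), per-plant-family pollination
   Pₓ = D·M·X / max(D·M·X), and cultural function C = Y / max(Y) — each
   scaled so the top species scores exactly 1;
4. tests whether function scores, and mean patristic distances from a set
   of candidate phylogenies, are associated with the dynamics distance
   matrix via one-tailed **permutation Mantel tests** (default 9,999
   permutations) with species-bootstrap 95% confidence limits.

A synthetic-community generator (`simulate_community()`) produces abundance
matrices, tree sets and trait tables with known guild structure,
phylogenetically heritable driver loadings and clustered-or-dispersed
function scenarios, so every stage of the pipeline is testable end to end
without access to monitoring-scheme data.

## Worked example

```r
library(respguild)

## a community of 20 species in 4 response guilds, 40 years of indices
cfg <- community_config(n_species = 20, n_years = 40, n_guilds = 4,
                        within_guild_rho = 0.7, seed = 2026)
sim <- simulate_community(cfg)
sim$abundance
#> Abundance matrix: 20 species x 40 years ( 1976 - 2015 ), 40 missing cells

## dynamics distances -> dendrogram -> guilds
dd <- dynamics_distance(sim$abundance, min_pairs = 5)
guilds <- cut_dendrogram(build_linkage(dd$d), k = 4)
guilds
#> Guild allocation for 20 species; resolutions: k=4 -> 4 guilds
guild_recovery_score(guilds, sim$truth$guild_of[guilds$species])
#> [1] 1

## heritability: do related species have similar dynamics?
cfgb <- community_config(n_species = 20, n_years = 40, n_guilds = 4,
                         within_guild_rho = 0.7,
                         heritability_mode = "brownian_loadings",
                         n_trees = 50, seed = 2026)
simb <- simulate_community(cfgb)
ddb <- dynamics_distance(simb$abundance, min_pairs = 5)
al <- align_matrices(ddb$d, average_patristic(simb$trees))
mantel_test(al$m1, al$m2, n_perm = 9999, n_boot = 500, seed = 2026)
#> Mantel test (greater): r = 0.3147, p = 0.0031 (n = 20 species, 9999 permutations)
#>   bootstrap 95% CL: [0.0947, 0.6091] (500 resamples)
```

The adjusted Rand index of 1 says the dendrogram cut recovered the four
simulated guilds exactly. The Mantel r of 0.31 with p ≈ 0.003 says greater
patristic distance goes with greater dynamics distance — population
responses are phylogenetically heritable in this simulated community, as
designed.

For a full run — guild tables at several resolutions, all production
functions, and one Mantel row per comparison written to disk with
provenance headers — write the inputs with `write_community()` and call
`run_full_analysis(run_config(...), out_dir)`; see `?run_full_analysis`.

The per-species function scores published for the 54 UK butterfly species
ship as a plain-text fixture:
`read_function_score_table()` returns the 54 × 5 score table (biomass,
cultural, general/Brassicaceae/Caryophyllaceae pollination), with censored
`<0.001` entries flagged.

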