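#!/usr/bin/env Rscript

# Stage 4: the source-tracking core. On NON-rarefied counts: detection of
# each pool's presence set, prevalence/UpSet intersections, origin
# assignment of every seedling ASV (seed / soil / both / unknown),
# transmission success per source pool, class-wise transmission rates
# (rare < 0.01%, intermediate, abundant > 1%), and the source-vs-seedling
# abundance pairing at d14.

suppressMessages(library(seedtrans))

seed <- 42L
ft <- read_feature_table("results/simulated/feature_table.tsv")
ft <- feature_table(ft$counts,
                    metadata = read_sample_metadata("results/simulated/metadata.tsv"))
config <- pipeline_config(rng_seed = seed)

tx <- transmission_analysis(ft, config)
write_result_tables(tx, "results/transmission", config = config, seed = seed,
                    overwrite = TRUE)

cat("Detected source pool sizes:\n")
print(tx$pool_sizes, row.names = FALSE)

cat("\nMean origin composition of seedling communities (over",
    length(unique(paste(tx$origin_fractions$compartment, tx$origin_fractions$soil,
                        tx$origin_fractions$genotype, tx$origin_fractions$year,
                        tx$origin_fractions$stage))), "contexts):\n")
of <- aggregate(cbind(membership, abundance) ~ category, tx$origin_fractions, mean)
of$membership <- round(100 * of$membership, 1)
of$abundance <- round(100 * of$abundance, 1)
names(of) <- c("category", "membership_pct", "abundance_pct")
print(of, row.names = FALSE)

cat("\nTransmission success at d14 (% of source pool, mean over contexts):\n")
tr <- tx$transmission[tx$transmission$stage == "d14", ]
ts <- aggregate(mean ~ source_type + source + compartment, tr,
                function(x) round(mean(x), 1))
print(ts[order(ts$source_type, ts$source), ], row.names = FALSE)

cat("\nClass-wise soil transmission rates (% of class, mean over contexts):\n")
cr <- tx$class_rates[tx$class_rates$source_type == "soil", ]
cw <- aggregate(percentage ~ compartment + class, cr,
                function(x) round(mean(x, na.rm = TRUE), 1))
print(cw[order(cw$compartment, cw$class), ], row.names = FALSE)

cat("\nAbundance pairing at d14:",
    sum(tx$pairing$above_line), "of", nrow(tx$pairing),
    "transmitted ASVs are more abundant in the seedling than in their source;",
    sum(tx$pairing$became_abundant), "became abundant (>1%).\n")
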