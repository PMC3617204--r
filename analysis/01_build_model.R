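#!/usr/bin/env Rscript
# Build the reference CD4+ T cell differentiation network, validate its
# structure (93 species / 52 reactions / 60 ODEs) and export it in SBML and
# auditable JSON form.

library(cd4sim)
dir.create("results", showWarnings = FALSE)

model <- build_reference_model()
v <- validate_model(model)
print(v)
stopifnot(v$pass)

write_sbml(model, "results/cd4_model.sbml.xml")
write_model_json(model, "results/cd4_model.json")
write.csv(data.frame(quantity = names(v$counts), value = unname(v$counts)),
          "results/01_structural_counts.csv", row.names = FALSE)

cat("\nModel exported to results/cd4_model.sbml.xml (SBML L3V2) and",
    "results/cd4_model.json.\n")
cat("Round-trip check:",
    n_species(read_sbml("results/cd4_model.sbml.xml")) == 93, "\n")
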