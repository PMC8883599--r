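# Canonical nutrient order. The first 11 ("constrained") enter the LP as
# >= constraints; the last 4 ("reported") are tracked in totals only.
.CONSTRAINED <- c(
  "protein", "calcium", "choline", "fibre", "iron", "magnesium",
  "potassium", "vit_a", "vit_c", "vit_d", "vit_e"
)
.REPORTED <- c("energy", "sodium", "added_sugars", "sat_fat")
.NUTRIENTS <- c(.CONSTRAINED, .REPORTED)

.NUTRIENT_UNITS <- c(
  protein = "g", calcium = "mg", choline = "mg", fibre = "g", iron = "mg",
  magnesium = "mg", potassium = "mg", vit_a = "ug_rae", vit_c = "mg",
  vit_d = "ug", vit_e = "mg", energy = "kJ", sodium = "mg",
  added_sugars = "g", sat_fat = "g"
)

# food-table column name for each nutrient (per 100 g basis)
.NUTRIENT_COLS <- c(
  protein = "protein_g", calcium = "calcium_mg", choline = "choline_mg",
  fibre = "fibre_g", iron = "iron_mg", magnesium = "magnesium_mg",
  potassium = "potassium_mg", vit_a = "vit_a_ug_rae", vit_c = "vit_c_mg",
  vit_d = "vit_d_ug", vit_e = "vit_e_mg", energy = "energy_kj",
  sodium = "sodium_mg", added_sugars = "added_sugars_g", sat_fat = "sat_fat_g"
)

.KJ_PER_KCAL <- 4.184
.G_ADDED_SUGAR_PER_TSP <- 4.2
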