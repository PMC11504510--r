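options:
  sugar_energy_factor_kcal_per_g: 4.0
  kj_per_kcal: 4.184
  age_min_label_months: 6.0
  pouch_rules: yes
  preparation_rules: yes
subcategories:
  '1.1':
    label: Dry cereals and starches, plain
    product_group: dry cereals and starches
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: no
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '1.2':
    label: Dry cereals and starches with added fruit
    product_group: dry cereals and starches
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    protein_min_g_per_100kcal: 3.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '2.1':
    label: Dairy-based foods, desserts, and cereals
    product_group: dairy foods
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_flag_threshold_pct_energy: 40.0
    protein_min_g_per_100kcal: 3.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '2.2':
    label: Fruit-containing product, including breakfast/dairy
    product_group: dairy foods
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_flag_threshold_pct_energy: 40.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '3.1':
    label: Fruit only products
    product_group: fruit and vegetable purees
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_flag_threshold_pct_energy: 40.0
    fruit_required_pct: 100.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '3.2':
    label: Vegetable only products
    product_group: fruit and vegetable purees
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    added_water_max_pct: 25.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '3.3':
    label: Fruit/vegetable products with other ingredients
    product_group: fruit and vegetable purees
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_flag_threshold_pct_energy: 40.0
    protein_min_g_per_100kcal: 3.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '3.4':
    label: Mixed fruit and vegetable only products
    product_group: fruit and vegetable purees
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_flag_threshold_pct_energy: 40.0
    added_water_max_pct: 25.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '4.1':
    label: Food with cheese named but no protein
    product_group: savoury meals
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    protein_min_g_per_100kcal: 3.0
    protein_min_pct_weight: 4.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '4.2':
    label: Food with protein named
    product_group: savoury meals
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    protein_min_g_per_100kcal: 3.0
    protein_min_pct_weight: 4.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '4.3':
    label: Food without protein or cheese named
    product_group: savoury meals
    energy_min_kcal_per_100g: 60.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    protein_min_g_per_100kcal: 3.0
    protein_min_pct_weight: 4.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: yes
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '5.1':
    label: Dry or semi-dry snacks and finger foods
    product_group: snacks and finger foods
    energy_max_kcal_per_serve: 50.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: no
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '5.2':
    label: Other snacks and finger foods
    product_group: snacks and finger foods
    energy_max_kcal_per_serve: 50.0
    sodium_max_mg_per_100kcal_base: 50.0
    sodium_max_mg_per_100kcal_cheese: 100.0
    sugar_max_pct_energy: 15.0
    fat_max_g_per_100kcal: 4.5
    fruit_declaration_required: no
    added_sugar_prohibited: yes
    trans_fat_prohibited: yes
    category_permitted: yes
  '6.1':
    label: Confectionery
    product_group: confectionery
    fruit_declaration_required: no
    added_sugar_prohibited: no
    trans_fat_prohibited: no
    category_permitted: no
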