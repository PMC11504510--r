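column,type,detail
product_id,character,unique identifier
brand,character,brand name
name_text,character,product name as printed
subcategory,character,"NPPM subcategory code, e.g. '3.2'"
product_group,character,"one of: dry cereals and starches, dairy foods, fruit and vegetable purees, savoury meals, snacks and finger foods, confectionery"
package_type,character,"one of: pouch, jar, bowl, single-serve packet/sachet, multi-serve box/packet"
has_spout,logical,TRUE for spouted pouches
serve_size_g,numeric,grams per serve (> 0)
energy_kcal_per_100g,numeric,kcal per 100 g (>= 0)
total_sugar_g_per_100g,numeric,g per 100 g (0-100)
sodium_mg_per_100g,numeric,mg per 100 g (>= 0)
protein_g_per_100g,numeric,g per 100 g (>= 0)
total_fat_g_per_100g,numeric,g per 100 g (>= 0)
industrial_trans_fat_present,logical,industrially produced trans fat in ingredients
added_free_sugars_present,logical,added free sugars or sweeteners in ingredients
fruit_pct,numeric,% fruit by weight (0-100) or missing
added_water_pct,numeric,% added water (0-100) or missing
fruit_amount_declared,logical,amount of fruit declared on label where fruit present
water_amount_declared,logical,amount of added water declared on label where water added
cheese_named,logical,cheese named in the product name
protein_named,logical,protein named in the product name
requires_preparation,logical,product requires preparation before serving
claims,list,'category: text' pairs separated by ' ; ' in CSV
ingredients_descending_order,logical,ingredient list in descending order by weight
ingredient_list_amounts_complete,logical,ingredient list declares amounts of added water/fruit
age_min_months,numeric,"labelled minimum age, months (0-48) or missing"
age_max_months,numeric,"labelled upper age, months (0-48) or missing"
breastfeeding_statement_present,logical,statement on continued breastfeeding present
spoon_or_bowl_suggestion,logical,suggestion to serve from a spoon or bowl
no_spout_consumption_instruction,logical,explicit instruction not to consume from the spout
on_the_go_claim_present,logical,'on-the-go' convenience claim present
preparation_instructions_present,logical,preparation instructions present
preparation_instructions_suitable,logical,preparation instructions classified suitable
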