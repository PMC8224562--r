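label,annotation,citation_keys
balanced,"Balanced macronutrient profile; associated with reduced risk of obesity and metabolic disease",B43
high_protein,"Higher protein with moderate fat and carbohydrate; favorable for weight management",B30
high_carbohydrate,"High carbohydrate share; sustained high-carbohydrate diets are not beneficial to weight loss under equal calories",B31
high_sugar,"High refined sugar; excess intake linked to raised triglycerides, total cholesterol, blood pressure and cardiovascular disease",B32;B44;B33;B34
high_sodium,"High sodium (salt); associated with hypertension, cardiovascular disease and chronic kidney disease",B35;B36;B37
high_fiber,"High dietary fiber; higher intake associated with reduced risk of cardiovascular disease, type 2 diabetes and cancer",B38;B17;B39
high_fat,"High overall fat; health impact depends on fat quality - unsaturated oils (olive, etc.) can reduce stroke and cardiovascular risk",B40;B41
high_saturated_fat,"High saturated fat; higher prevalence of cardiovascular disease, especially combined with refined starch",B42
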