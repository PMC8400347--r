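brand,code,cycle,ingredients,kcal_per_8floz_mfr,ingredients_known
Apple and Eve juice drinks,92530610,2013-2016-combined,None,110,TRUE
Florida's Naturals juice cocktails,92530610,2013-2016-combined,None,130,TRUE
Hawaiian Punch (Green Berry Rush),92530610,2013-2016-combined,sucralose; acesulfame potassium,60,TRUE
Hawaiian Punch (Fruit Juicy Red),92530610,2013-2016-combined,sucralose,60,TRUE
Hi-C,92530610,2013-2016-combined,None,110,TRUE
Kool-Aid Jammers,92530610,2013-2016-combined,sucralose,30,TRUE
Minute Maid (10-20 fl oz bottle or 2 L bottle or 12 fl oz can),92530610,2013-2016-combined,None,110,TRUE
Minute Maid (128 fl oz bottle or 59 oz can),92530610,2013-2016-combined,sucralose,90,TRUE
Minute Maid Coolers,92530610,2013-2016-combined,None,120,TRUE
"Ocean Spray juice drink or cocktail, flavors other than cranberry",92530610,2013-2016-combined,None,110,TRUE
Ssips,92530610,2013-2016-combined,None,120,TRUE
Tropicana fruit punch,92530610,2013-2016-combined,None,130,TRUE
"Tropicana Lemonade, chilled carton",92530610,2013-2016-combined,None,120,TRUE
"Tropicana Twister, all flavors except lemonade",92530610,2013-2016-combined,None,140,TRUE
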