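code,cycle,main_description,additional_description,wweia_category,kcal_per_100g,grams_per_floz
92550030,2013-2016-combined,"Fruit juice drink, with high vitamin C, light","Light Hawaiian Punch; Minute Maid Light juice drinks; Tropicana Light lemonade",7204,19.17,30
92550035,2013-2016-combined,"Fruit juice drink, light","Minute Maid Light fruit punch; Sunsweet prune juice light; Plumsmart Light plum juice",7204,39.17,30
92550040,2013-2016-combined,"Fruit juice drink, diet","Diet Snapple juice drinks, all flavors",7204,19.17,30
92550110,2013-2016-combined,"Cranberry juice drink, with high vitamin C, light","Ocean Spray Light Cranberry Juice Cocktail; Apple and Eve Light Cranberry juice drinks",7204,19.17,30
92550200,2013-2016-combined,"Grape juice drink, light","Welch's Light juice drinks",7204,20.84,30
92550350,2013-2016-combined,"Orange juice beverage, 40-50% juice, light","Tropicana Trop 50; Minute Maid Light; Dole Light",7204,20.84,30
92550360,2013-2016-combined,"Apple juice beverage, 40-50% juice, light","Tropicana Trop 50; Mott's Light",7204,22.92,30
92550370,2013-2016-combined,"Lemonade, fruit juice drink, light","Tropicana Trop 50 Lemonade",7204,21.67,30
92550380,2013-2016-combined,"Pomegranate juice beverage, 40-50% juice, light","POM Lite, all flavors",7204,54.17,30
92550400,2013-2016-combined,"Vegetable and fruit juice drink, with high vitamin C, diet","Diet V8 Splash, all flavors, low calorie",7106,4.17,30
92550405,2013-2016-combined,"Vegetable and fruit juice drink, with high vitamin C, light","V8 V-Fusion Light, all flavors",7204,4.17,30
92550610,2013-2016-combined,"Fruit flavored drink, with high vitamin C, diet","Diet Ocean Spray cranberry, blueberry, or pomegranate blends",7106,2.08,30
92550620,2013-2016-combined,"Fruit flavored drink, diet","Crystal Light; Minute Maid Light",7106,4.17,30
92552000,2013-2016-combined,"Fruit flavored drink, with high vitamin C, powdered, reconstituted, diet","Sugar Free Tang; Country Time Lite lemonade; Ocean Spray drink mix, low calorie",7106,2.08,30
92552010,2013-2016-combined,"Fruit flavored drink, powdered, reconstituted, diet","Crystal Light; Sugar Free Kool-Aid; Wyler's Light",7106,2.08,30
92552020,2013-2016-combined,"Sunny D, reduced sugar","Reduced Sugar Sunny Delight fruit juice drink, all flavors",7204,2.08,30
92552030,2013-2016-combined,"Capri Sun, fruit juice drink","Capri Sun, NFS, 25% less sugar",7204,40.42,30
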