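brand,code,cycle,ingredients,kcal_per_8floz_mfr,ingredients_known
Light Hawaiian Punch,92550030,2013-2016-combined,sucralose; acesulfame potassium,10,TRUE
Minute Maid Light juice drinks,92550030,2013-2016-combined,aspartame; acesulfame potassium,15,TRUE
Tropicana Light lemonade,92550030,2013-2016-combined,sucralose; aspartame; acesulfame potassium,10,TRUE
Minute Maid Light fruit punch,92550035,2013-2016-combined,aspartame; acesulfame potassium,15,TRUE
Sunsweet prune juice light,92550035,2013-2016-combined,sucralose,100,TRUE
Plumsmart Light plum juice,92550035,2013-2016-combined,sucralose,60,TRUE
"Diet Snapple juice drinks, all flavors",92550040,2013-2016-combined,aspartame,10,TRUE
Ocean Spray Light Cranberry Juice Cocktail,92550110,2013-2016-combined,sucralose,50,TRUE
Apple and Eve Light Cranberry juice drinks,92550110,2013-2016-combined,sucralose; acesulfame potassium,10,TRUE
Welch's Light juice drinks,92550200,2013-2016-combined,sucralose; acesulfame potassium,45,TRUE
Tropicana Trop 50,92550350,2013-2016-combined,rebaudioside a,50,TRUE
Minute Maid Light,92550350,2013-2016-combined,sucralose; acesulfame potassium,50,TRUE
Dole Light,92550350,2013-2016-combined,,NA,FALSE
Tropicana Trop 50,92550360,2013-2016-combined,rebaudioside a,50,TRUE
Mott's Light,92550360,2013-2016-combined,sucralose,50,TRUE
Tropicana Trop 50 Lemonade,92550370,2013-2016-combined,rebaudioside a,50,TRUE
"POM Lite, all flavors",92550380,2013-2016-combined,None,75,TRUE
"Diet V8 Splash, all flavors, low calorie",92550400,2013-2016-combined,sucralose; acesulfame potassium,10,TRUE
"V8 V-Fusion Light, all flavors",92550405,2013-2016-combined,sucralose,50,TRUE
"Diet Ocean Spray cranberry, blueberry, or pomegranate blends",92550610,2013-2016-combined,acesulfame potassium; sucralose,5,TRUE
Crystal Light,92550620,2013-2016-combined,sucralose; acesulfame potassium,5,TRUE
Minute Maid Light,92550620,2013-2016-combined,aspartame; acesulfame potassium,15,TRUE
Sugar Free Tang (On-the-Go),92552000,2013-2016-combined,aspartame; acesulfame potassium,5,TRUE
Country Time Lite lemonade,92552000,2013-2016-combined,sucralose; acesulfame potassium; neotame,35,TRUE
"Ocean Spray drink mix, low calorie",92552000,2013-2016-combined,aspartame; acesulfame potassium,5,TRUE
Crystal Light,92552010,2013-2016-combined,aspartame; acesulfame potassium; rebiana,5,TRUE
Sugar Free Kool-Aid,92552010,2013-2016-combined,aspartame; acesulfame potassium,5,TRUE
Wyler's Light,92552010,2013-2016-combined,aspartame; acesulfame potassium,5,TRUE
"Reduced Sugar Sunny Delight fruit juice drink, all flavors",92552020,2013-2016-combined,sucralose; acesulfame potassium; neotame,60,TRUE
"Capri Sun, NFS, 25% less sugar",92552030,2013-2016-combined,None,94,TRUE
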