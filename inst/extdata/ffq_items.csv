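item_id,name,food_group,portion_code,food_g,flour_g
pandesal,Pandesal roll,breads,S,25,14
pandesal,Pandesal roll,breads,M,50,28
pandesal,Pandesal roll,breads,L,75,42
loaf_bread,Sliced loaf bread,breads,S,24,13
loaf_bread,Sliced loaf bread,breads,M,48,26
loaf_bread,Sliced loaf bread,breads,L,72,39
monay,Monay bun,breads,S,40,22
monay,Monay bun,breads,M,60,33
monay,Monay bun,breads,L,90,50
ensaymada,Ensaymada,breads,S,40,18
ensaymada,Ensaymada,breads,M,65,29
ensaymada,Ensaymada,breads,L,90,41
spanish_bread,Spanish bread,breads,S,30,16
spanish_bread,Spanish bread,breads,M,55,30
spanish_bread,Spanish bread,breads,L,80,44
cheese_bread,Cheese bread,breads,S,35,17
cheese_bread,Cheese bread,breads,M,55,27
cheese_bread,Cheese bread,breads,L,80,39
burger_bun,Burger bun,breads,S,40,22
burger_bun,Burger bun,breads,M,60,33
burger_bun,Burger bun,breads,L,85,47
hotdog_bun,Hotdog bun,breads,S,35,19
hotdog_bun,Hotdog bun,breads,M,50,28
hotdog_bun,Hotdog bun,breads,L,70,39
instant_noodles,Instant noodle soup,noodles,S,120,24
instant_noodles,Instant noodle soup,noodles,M,200,40
instant_noodles,Instant noodle soup,noodles,L,300,60
pancit_canton,Pancit canton,noodles,S,100,30
pancit_canton,Pancit canton,noodles,M,180,54
pancit_canton,Pancit canton,noodles,L,260,78
mami,Mami noodles,noodles,S,110,26
mami,Mami noodles,noodles,M,190,46
mami,Mami noodles,noodles,L,280,67
spaghetti,Spaghetti,noodles,S,100,28
spaghetti,Spaghetti,noodles,M,180,50
spaghetti,Spaghetti,noodles,L,270,76
misua,Misua soup,noodles,S,90,18
misua,Misua soup,noodles,M,160,32
misua,Misua soup,noodles,L,240,48
soda_crackers,Soda crackers,crackers,S,15,10
soda_crackers,Soda crackers,crackers,M,30,20
soda_crackers,Soda crackers,crackers,L,45,29
fita_crackers,Savoury crackers,crackers,S,15,9
fita_crackers,Savoury crackers,crackers,M,30,19
fita_crackers,Savoury crackers,crackers,L,45,28
graham_crackers,Graham crackers,crackers,S,14,9
graham_crackers,Graham crackers,crackers,M,28,18
graham_crackers,Graham crackers,crackers,L,42,27
marie_biscuits,Marie biscuits,crackers,S,12,8
marie_biscuits,Marie biscuits,crackers,M,24,16
marie_biscuits,Marie biscuits,crackers,L,36,24
mamon,Sponge cake (mamon),cakes,S,35,13
mamon,Sponge cake (mamon),cakes,M,55,21
mamon,Sponge cake (mamon),cakes,L,80,30
cupcake,Cupcake,cakes,S,30,12
cupcake,Cupcake,cakes,M,50,20
cupcake,Cupcake,cakes,L,75,30
brownie,Brownie,cakes,S,30,10
brownie,Brownie,cakes,M,50,17
brownie,Brownie,cakes,L,70,24
hopia,Hopia,cakes,S,30,13
hopia,Hopia,cakes,M,45,20
hopia,Hopia,cakes,L,65,29
banana_cake,Banana cake slice,cakes,S,40,14
banana_cake,Banana cake slice,cakes,M,60,21
banana_cake,Banana cake slice,cakes,L,85,30
egg_pie,Egg pie slice,cakes,S,45,14
egg_pie,Egg pie slice,cakes,M,70,21
egg_pie,Egg pie slice,cakes,L,100,30
siopao,Siopao,other,S,60,20
siopao,Siopao,other,M,100,33
siopao,Siopao,other,L,140,46
empanada,Empanada,other,S,50,18
empanada,Empanada,other,M,80,29
empanada,Empanada,other,L,110,40
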