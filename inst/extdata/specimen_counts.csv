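subfamily,genus,species,n,location,source,diet
Calliphorinae,Calliphora,Calliphora livida,21,"Everett, WA, USA",wild,rat
Calliphorinae,Calliphora,Calliphora vicina,20,"Everett, WA, USA",wild,rat
Calliphorinae,Calliphora,Calliphora vicina,57,"Everett, WA, USA",wild,rat
Chrysomyinae,Chrysomya,Chrysomya megacephala,30,"Miami, FL, USA",wild,chicken
Chrysomyinae,Cochliomyia,Cochliomyia hominivorax,11,"Pacora, Panama",culture,artificial diet
Chrysomyinae,Cochliomyia,Cochliomyia macellaria,40,"Lincoln, NE, USA",wild,pig
Calliphorinae,Cynomya,Cynomya cadaverina,76,"Lincoln, NE, USA",wild,raccoon
Luciliinae,Lucilia,Lucilia coeruleiviridis,14,"Lincoln, NE, USA",wild,rabbit
Luciliinae,Lucilia,Lucilia sericata,35,"Lincoln, NE, USA",culture,beef liver
Luciliinae,Lucilia,Lucilia sericata,64,"Lincoln, NE, USA",wild,rat
Chrysomyinae,Phormia,Phormia regina,39,"Lincoln, NE, USA",wild,pig
Chrysomyinae,Phormia,Phormia regina,28,"Everett, WA, USA",wild,rat
Chrysomyinae,Phormia,Phormia regina,39,"Lincoln, NE, USA",culture,beef liver
Chrysomyinae,Protophormia,Protophormia terraenovae,31,"Bonners Ferry, ID, USA",culture,fish meal
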