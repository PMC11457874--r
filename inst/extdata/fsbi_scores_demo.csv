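"taxon","score"
"Drunella doddsii",13
"Drunella coloradensis",12
"Epeorus",10
"Rhithrogena",10
"Cinygmula",8
"Caudatella",11
"Yoraperla",9
"Megarcys",10
"Doroneuria",9
"Sweltsa",7
"Neothremma",8
"Parapsyche",9
"Arctopsyche",7
"Glossosoma",6
"Dicosmoecus",6
"Oligophlebodes",7
"Ameletus",6
"Heterlimnius",6
"Narpus",6
"Cleptelmis",6
"Baetis",2
"Ephemerella",4
"Serratella",4
"Hydropsyche",3
"Brachycentrus",5
"Lepidostoma",4
"Micrasema",5
"Optioservus",3
"Zaitzevia",3
"Antocha",2
"Chironomus",0
"Oligochaeta",0
"Simulium",1
"Tricorythodes",1
"Physa",0
"Pisidium",0
"Hyalella",0
"Sphaerium",0
"Cricotopus",1
"Corixidae",0
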