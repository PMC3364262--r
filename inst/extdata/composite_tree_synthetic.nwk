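((Falcarius:55,Neimongosaurus:100,Oviraptor:100,Tyrannosaurus:100):55,((Anchiornis:22.5,Bambiraptor:67.5,Velociraptor:67.5):22.5,(Archaeopteryx:10,(Confuciusornis:31,(Eoconfuciusornis:27,(Sapeornis:23,(Zhongjianornis:19,((Cathayornis:7.5,Concornis:7.5,Eoalulavis:7.5,Iberomesornis:7.5,Longipteryx:7.5,Noguerornis:7.5,Pengornis:7.5,Protopteryx:7.5,Rapaxavis:7.5,Vescornis:7.5):7.5,(Hongshanornis:7.5,Longicrusavis:7.5,Ornithuromorpha_indet:7.5,Gansus:7.5,(((Anas_platyrhynchos:33.33333333,Cygnus_olor:33.33333333,Oxyura_australis:33.33333333):33.33333333,Chauna_torquata:66.66666667):33.33333333,Hirundapus_caudacutus:100,(Eurostopodus_mystacalis:50,Podargus_strigoides:50):50,(Cerorhinca_monocerata:66.66666667,Esacus_giganteus:66.66666667,Vanellus_miles:66.66666667,Chionis_minor:66.66666667,Stiltia_isabella:66.66666667,Larus_novaehollandiae:66.66666667,Recurvirostra_novaehollandiae:66.66666667,Rostratula_benghalensis:66.66666667,Rynchops_niger:66.66666667,(Limosa_lapponica:33.33333333,Numenius_arquata:33.33333333):33.33333333,Stercorarius_skua:66.66666667):33.33333333,((Leptoptilos_dubius:33.33333333,Mycteria_americana:33.33333333):33.33333333,Threskiornis_spinicollis:66.66666667,Ajaja_ajaja:66.66666667):33.33333333,Phaps_elegans:100,(Megaceryle_torquata:50,Dacelo_novaeguineae:50,Momotus_momota:50):50,Cuculus_canorus:100,((Accipiter_fasciatus:33.33333333,Circus_cyaneus:33.33333333,Geranospiza_caerulescens:33.33333333,Pandion_haliaetus:33.33333333):33.33333333,(Falco_peregrinus:33.33333333,Falco_rusticolus:33.33333333,Herpetotheres_cachinnans:33.33333333):33.33333333,Sagittarius_serpentarius:66.66666667):33.33333333,(Macrocephalon_maleo:66.66666667,Leipoa_ocellata:66.66666667,(Guttera_plumifera:33.33333333,Numida_meleagris:33.33333333):33.33333333,(Argusianus_agrus:33.33333333,Coturnix_pectoralis:33.33333333):33.33333333):33.33333333,(Ardeotis_australis:50,Fulica_atra:50):50,(Coracina_novaehollandiae:66.66666667,Corcorax_melanoramphos:66.66666667,(Corvus_coronoides:33.33333333,Corvus_mellori:33.33333333,Corvus_ossifragus:33.33333333):33.33333333,Tityra_semifasciata:66.66666667,Gymnorhina_tibicen:66.66666667,Grallina_cyanoleuca:66.66666667,Menura_novaehollandiae:66.66666667,Colluricincla_harmonica:66.66666667,Oriolus_sagittatus:66.66666667,Ptilonorhynchus_violaceus:66.66666667,Sturnus_vulgaris:66.66666667,Tyrannus_melancholicus:66.66666667):33.33333333,((Anhinga_novaehollandiae:33.33333333,Anhinga_rufa:33.33333333):33.33333333,(Ardea_pacifica:33.33333333,Cochlearius_cochlearius:33.33333333):33.33333333,Phalacrocorax_carbo:66.66666667,(Morus_bassanus:33.33333333,Morus_serrator:33.33333333):33.33333333):33.33333333,Phaethon_rubricauda:100,Phoenicopterus_ruber:100,Colaptes_auratus_cafer:100,(Aechmophorus_occidentalis:50,Podiceps_cristatus:50):50,(Thalassarche_chrysostoma:66.66666667,(Diomedea_epomophora:33.33333333,Diomedea_immutabilis:33.33333333):33.33333333,Pagodroma_nivea:66.66666667,Pelecanoides_urinatrix:66.66666667,Pterodroma_macroptera:66.66666667):33.33333333,(Cacatua_sanguinea:50,Anodorhynchus_hyacinthinus:50):50,(Aptenodytes_patagonicus:50,Eudyptes_chryosolophus:50,Eudyptes_chrysocome:50,Spheniscus_humboldti:50):50,((Ninox_novaeseelandiae:33.33333333,Pulsatrix_perspicellata:33.33333333):33.33333333,Tyto_alba:66.66666667):33.33333333,(Crypturellus_cinnamomeus:50,Tinamus_major:50):50)Neornithes:32.5):7.5)Ornithothoraces:4):4):4):4):4)Aves:10)Paraves:65)Theropoda;
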