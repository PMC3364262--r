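taxon,order,family,common_name,id,flight_mode,no
Accipiter fasciatus,Falconiformes,Accipitridae,Brown Goshawk,MV W6645,FG,1
Aechmophorus occidentalis,Podicipediformes,Podicipedidae,Western Grebe,YPM 104291,CF,2
Ajaja ajaja,Ciconiiformes,Threskiornithidae,Roseate Spoonbill,YPM 102558,FG,3
Anas platyrhynchos,Anseriformes,Anatidae,Mallard,AMNH 5847,CF,4
Anhinga novaehollandiae,Pelecaniformes,Anhingidae,Australasian Darter,MV B8674,SS,5
Anhinga rufa,Pelecaniformes,Anhingidae,African Darter,YPM 103994,S,6
Anodorhynchus hyacinthinus,Psittaciformes,Psittacidae,Hyacinth Macaw,MCZ 346739,CF,7
Aptenodytes patagonicus,Sphenisciformes,Spheniscidae,King Penguin,MCZ 347208,SUB,8
Ardea pacifica,Pelecaniformes,Ardeidae,White-necked Heron,MV B6820,CF,9
Ardeotis australis,Gruiformes,Otididae,Australian Bustard,MV B8566,PF,10
Argusianus agrus,Galliformes,Phasianidae,Great Argus,AMNH 4969,CF,11
Cacatua sanguinea,Psittaciformes,Cacatuidae,Little Corella,MV W5474,CF,12
Cerorhinca monocerata,Charadriiformes,Alcidae,Rhinoceros Auklet,MV B12388,CF,13
Chauna torquata,Anseriformes,Anhimidae,Southern Screamer,AMNH 3616,CF,14
Chionis minor,Charadriiformes,Chionididae,Black-faced Sheathbill,MV W3457,CF,15
Circus cyaneus,Falconiformes,Accipitridae,Hen Harrier,MCZ 342125,S,16
Cochlearius cochlearius,Pelecaniformes,Ardeidae,Boat-billed Heron,AMNH 3494,CF,17
Colaptes auratus cafer,Piciformes,Picidae,Red-shafted Flicker,MV B12384,CF,18
Colluricincla harmonica,Passeriformes,Muscicapidae,Grey Shrikethrush,MV B12031,IB,19
Coracina novaehollandiae,Passeriformes,Campephagidae,Black-faced Cuckoo-shrike,MV B10770,IB,20
Corcorax melanoramphos,Passeriformes,Corcoracidae,White-winged Chough,MV B11506,IB,21
Corvus coronoides,Passeriformes,Corvidae,Australian Raven,MV R7711,FG,22
Corvus mellori,Passeriformes,Corvidae,Little Raven,MV B10351,FG,23
Corvus ossifragus,Passeriformes,Corvidae,Fish Crow,AMNH 1050,FG,24
Coturnix pectoralis,Galliformes,Phasianidae,Stubble Quail,MV B9799,PF,25
Crypturellus cinnamomeus,Tinamiformes,Tinamidae,Thicket Tinamou,MV B4785,PF,26
Cuculus canorus,Cuculiformes,Cuculidae,Common Cuckoo,YPM 105038,CF,27
Cygnus olor,Anseriformes,Anatidae,Mute Swan,MCZ 347051,CF,28
Dacelo novaeguineae,Coraciiformes,Halcyonidae,Laughing Kookaburra,MV B12052,CF,29
Diomedea epomophora,Procellariiformes,Diomedeidae,Southern Royal Albatross,AMNH 1437,S,30
Diomedea immutabilis,Procellariiformes,Diomedeidae,Laysan Albatross,MCZ 343050,S,31
Esacus giganteus,Charadriiformes,Burhinidae,Beach Stone-curlew,MV B6587,CF,32
Eudyptes chryosolophus,Sphenisciformes,Spheniscidae,Macaroni Penguin,YPM 102975,SUB,33
Eudyptes chrysocome,Sphenisciformes,Spheniscidae,Western Rockhopper Penguin,MCZ 346428,SUB,34
Eurostopodus mystacalis,Caprimulgiformes,Caprimulgidae,White-throated Nightjar,MV W6663,FG,35
Falco peregrinus,Falconiformes,Falconidae,Peregrine Falcon,MV W3765,FG,36
Falco rusticolus,Falconiformes,Falconidae,Gyrfalcon,MCZ 343335,FG,37
Fulica atra,Gruiformes,Rallidae,Eurasian Coot,MV W6361,CF,38
Geranospiza caerulescens,Falconiformes,Accipitridae,Crane Hawk,MCZ 343032,S,39
Grallina cyanoleuca,Passeriformes,Grallinidae,Magpie-lark,MV B11122,IB,40
Guttera plumifera,Galliformes,Numididae,Plumed Guineafowl,AMNH 6415,PF,41
Gymnorhina tibicen,Passeriformes,Cracticidae,Australian Magpie,MV B6540,FG,42
Herpetotheres cachinnans,Falconiformes,Falconidae,Laughing Falcon,MCZ 337109,FG,43
Hirundapus caudacutus,Apodiformes,Apodidae,White-throated Needletail,MV B11129,S,44
Larus novaehollandiae,Charadriiformes,Lariidae,Silver Gull,MV W6163,FG,45
Leipoa ocellata,Galliformes,Megapodiidae,Malleefowl,MV B9276,PF,46
Leptoptilos dubius,Ciconiiformes,Ciconiidae,Greater Adjutant,MV W5083,S,47
Limosa lapponica,Charadriiformes,Scolopacidae,Bar-tailed Godwit,MV W4133,CF,48
Macrocephalon maleo,Galliformes,Megapodidae,Maleo,MCZ 340355,PF,49
Megaceryle torquata,Coraciiformes,Cerylidae,Ringed Kingfisher,YPM 109939,FG,50
Menura novaehollandiae,Passeriformes,Menuridae,Superb Lyrebird,MV B12391,PF,51
Momotus momota,Coraciiformes,Momotidae,Blue-crowned Motmot,MV 31795,CF,52
Morus bassanus,Pelecaniformes,Sulidae,Northern Gannet,MCZ 347043,S,53
Morus serrator,Pelecaniformes,Sulidae,Australasian Gannet,MV W4734,S,54
Mycteria americana,Ciconiiformes,Ciconiidae,Wood Stork,AMNH 3768,S,55
Ninox novaeseelandiae,Strigiformes,Strigidae,Southern Boobook,MV B11547,FG,56
Numenius arquata,Charadriiformes,Scolopacidae,Eurasian Curlew,YPM 111466,CF,57
Numida meleagris,Galliformes,Numididae,Helmeted Guineafowl,MV W6355,PF,58
Oriolus sagittatus,Passeriformes,Oriolidae,Olive-backed Oriole,MV B8562,IB,59
Oxyura australis,Anseriformes,Anatidae,Blue-billed Duck,MV B5145,CF,60
Pagodroma nivea,Procellariiformes,Oceanitidae,Snow Petrel,MV R6590,FG,61
Pandion haliaetus,Falconiformes,Accipitridae,Osprey,MCZ 347607,S,62
Pelecanoides urinatrix,Procellariiformes,Pelecanoididae,Common Diving-petrel,MV B6759,CF,63
Phaethon rubricauda,Phaethontiformes,Phaethontidae,Red-tailed Tropicbird,YPM 110024,FG,64
Phalacrocorax carbo,Pelecaniformes,Phalacrocoracidae,Great Cormorant,MV W6577,CF,65
Phaps elegans,Columbiformes,Columbidae,Brush Bronzewing,MV B8568,CF,66
Phoenicopterus ruber,Phoenicopteriformes,Phoenicopteridae,American Flamingo,MV 8748,CF,67
Podargus strigoides,Caprimulgiformes,Podargidae,Tawny Frogmouth,MV B6595,FG,68
Podiceps cristatus,Podicipediformes,Podicipedidae,Great Crested Grebe,MV W4196,CF,69
Pterodroma macroptera,Procellariiformes,Procellariidae,Great-winged Petrel,MV B10118,S,70
Ptilonorhynchus violaceus,Passeriformes,Ptilonorhynchidae,Satin Bowerbird,MV W6490,CF,71
Pulsatrix perspicellata,Strigiformes,Strigidae,Spectacled Owl,MCZ 343002,FG,72
Recurvirostra novaehollandiae,Charadriiformes,Recurvirostridae,Red-necked Avocet,MV W6194,FG,73
Rostratula benghalensis,Charadriiformes,Rostratulidae,Greater Painted Snipe,MV B1196,CF,74
Rynchops niger,Charadriiformes,Rynchopidae,Black Skimmer,YPM 107666,CF,75
Sagittarius serpentarius,Falconiformes,Sagittariidae,Secretarybird,AMNH 4006,FG,76
Spheniscus humboldti,Sphenisciformes,Spheniscidae,Humboldt Penguin,MCZ 347040,SUB,77
Stercorarius skua,Charadriiformes,Stercorariidae,Great Skua,MV W6658,CF,78
Stiltia isabella,Charadriiformes,Glareolidae,Australian Pratincole,MV B8534,CF,79
Sturnus vulgaris,Passeriformes,Sturnidae,European Starling,MV B12039,IB,80
Thalassarche chrysostoma,Procellariiformes,Diomedeida,Grey-headed Albatross,MV B6731,S,81
Threskiornis spinicollis,Ciconiiformes,Plataleidae,Straw-necked Ibis,MV W3973,FG,82
Tinamus major,Tinamiformes,Tinamidae,Great Tinamou,MCZ 342774,PF,83
Tityra semifasciata,Passeriformes,Cotingidae,Masked Tityra,MV B10711,IB,84
Tyrannus melancholicus,Passeriformes,Tyrannidae,Tropical Kingbird,MV B10637,IB,85
Tyto alba,Strigiformes,Tytonidae,Barn Owl,MV B11415,FG,86
Vanellus miles,Charadriiformes,Charadriidae,Masked Lapwing,MV W1350,CF,87
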