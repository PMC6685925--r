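DOLPHIN
TIGER
ELEPHANT
GIRAFFE
PENGUIN
KANGAROO
RABBIT
HORSE
EAGLE
WOLF
BEAR
FOX
DEER
OTTER
SEAL
WHALE
SHARK
LIZARD
TURTLE
SNAKE
FROG
OWL
FALCON
HAWK
RAVEN
SPARROW
SWAN
GOOSE
DUCK
HERON
STORK
PELICAN
FLAMINGO
PARROT
TOUCAN
PEACOCK
OSTRICH
EMU
LLAMA
ALPACA
CAMEL
DONKEY
MULE
GOAT
SHEEP
COW
PIG
CHICKEN
ROOSTER
TURKEY
PIGEON
HAMSTER
GERBIL
GUINEAPIG
SQUIRREL
CHIPMUNK
BEAVER
PORCUPINE
HEDGEHOG
MOLE
SHREW
BAT
FERRET
WEASEL
BADGER
RACCOON
SKUNK
OPOSSUM
ARMADILLO
SLOTH
ANTEATER
TAPIR
HIPPO
RHINO
ZEBRA
GAZELLE
ANTELOPE
BUFFALO
BISON
MOOSE
ELK
REINDEER
CARIBOU
LYNX
BOBCAT
COUGAR
LEOPARD
JAGUAR
CHEETAH
PANTHER
LION
HYENA
JACKAL
COYOTE
DINGO
MONKEY
BABOON
GORILLA
CHIMPANZEE
ORANGUTAN
GIBBON
LEMUR
MEERKAT
MONGOOSE
OCELOT
SERVAL
CARACAL
WALRUS
MANATEE
DUGONG
NARWHAL
ORCA
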