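MICHAEL
SARAH
DAVID
LAURA
THOMAS
ANNA
PETER
JULIA
MARTIN
LENA
STEFAN
MARIE
ANDREAS
SOPHIE
CHRISTIAN
EMMA
DANIEL
LISA
MARKUS
NINA
FLORIAN
KATHARINA
SEBASTIAN
JOHANNA
ALEXANDER
THERESA
MAXIMILIAN
VANESSA
BENJAMIN
ISABELLA
JONAS
HANNAH
FELIX
CLARA
LUKAS
PAULA
SIMON
MIRIAM
PHILIPP
FRANZISKA
TOBIAS
VERENA
MATTHIAS
CORNELIA
OLIVER
BEATRICE
PATRICK
MELANIE
DOMINIK
ANGELIKA
RAPHAEL
VALENTINA
GEORG
MAGDALENA
KONRAD
ELISABETH
VIKTOR
CHARLOTTE
ADRIAN
VERONIKA
BERND
GABRIELE
CLEMENS
HELENE
ERWIN
INGRID
FABIAN
JASMIN
GREGOR
KRISTINA
HARALD
LARISSA
IGNAZ
MONIKA
JAKOB
NATALIE
KARL
OLIVIA
LEOPOLD
PETRA
MANUEL
REGINA
NORBERT
SILVIA
OSKAR
TAMARA
PAUL
URSULA
RICHARD
WILMA
SAMUEL
XENIA
THEODOR
YVONNE
ULRICH
ZITA
WERNER
AGNES
XAVER
BRIGITTE
ROBERT
CAROLINE
ERIK
DANIELA
FRANZ
EDITH
GUSTAV
FIONA
HEINRICH
GRETA
IVAN
HILDA
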