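the boy walked to the school with his friend
the girl read a book about the old house
my brother lost his journal a few weeks back
the dog ran across the yard and barked at the mailman
she put the diary on the table near the window
the teacher asked the class to write a story
he told his mother about the game after dinner
the family drove to the lake on a warm morning
the children played in the park until it was dark
grandpa told a long story about the farm
the cat slept on the chair in the kitchen
father fixed the door of the old barn
the boys carried the boxes up the stairs
she found the keys under the bed this morning
the class went to the museum on friday
he wrote a letter to his uncle about the trip
the rain fell all night on the quiet town
mother baked bread and the house smelled wonderful
the team won the game in the last minute
his sister borrowed the bike and rode to the store
they watched a movie about a brave captain
the old man fed the birds in the garden
the river ran past the edge of the village
we ate lunch outside under the big tree
the baby laughed at the funny clown
the librarian put the books back on the shelf
a loud noise woke the whole house at midnight
the farmer sold apples at the market in town
the students finished their homework before supper
the little girl drew a picture of her family
he forgot his hat on the bus again
the neighbors built a fence around their garden
the coach told the players to run another lap
she sang a song about the summer and the sea
the letter arrived two days after his birthday
the men loaded the truck with heavy bags
a small bird landed on the kitchen window
the kids traded cards during the lunch break
the story ended with a big surprise
my friend got a new puppy for his birthday
the teacher wrote the answer on the board
they walked home through the snow after school
the shop on the corner sells candy and toys
her mother told her to clean her room
the boat drifted slowly across the calm water
he hid the present in the back of the closet
the crowd cheered when the band started to play
the soup was too hot so he waited a while
the twins argued about who won the race
she promised to call her grandmother on sunday
the principal spoke to the parents in the gym
a storm knocked down the old tree by the road
the journal was full of secrets and funny drawings
he spent the whole weekend reading comic books
the bell rang and the students ran outside
the map showed a path through the forest
the brothers washed the car for some extra money
the nurse gave the boy a bandage for his knee
winter came early and the pond froze over
the play was about a king and his three sons
my uncle keeps his tools in the garage
the smell of cookies filled the whole kitchen
the bus was late so they walked to school
she planted flowers along the front walk
the dentist told him to brush his teeth every day
the lost wallet was returned by an honest stranger
the game was canceled because of the heavy rain
the scouts set up their tents near the river
he practiced the piano for an hour after school
the store ran out of milk before noon
the reporter asked the mayor a hard question
the painting in the hall was older than the house
the boy traded his sandwich for a cookie
the last chapter of the book made her cry
dad burned the toast again this morning
the club meets every tuesday in the library
a squirrel stole the bread from the picnic table
the new student sat alone at lunch
the fire truck raced down the main street
her essay won first prize at the fair
the moon rose over the hills behind the farm
he saved his allowance to buy a skateboard
the coach canceled practice because of the storm
the sisters shared a room at the top of the stairs
the juice spilled all over his math homework
the magician pulled a rabbit out of the hat
the family packed the car for the long trip
the leaves turned red and fell into the yard
he whispered the secret to his best friend
the puppy chewed a hole in the new couch
the choir sang at the school concert on thursday
the recipe called for two eggs and a cup of sugar
the kite got stuck in the tallest tree
the doctor said the boy could play again next week
the train left the station five minutes early
she wrapped the gift in bright paper
the janitor found a ring in the hallway
the news about the flood worried the farmers
the baker gave the children a free roll
the whole class laughed at the silly joke
the spelling test had twenty hard words
his boots were covered in mud from the field
the cousins built a fort out of old boards
the lights went out during the scary movie
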